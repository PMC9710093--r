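Package: vesselmorph
Title: Morphometric Analysis of 3D Microvasculature Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative morphometric analysis of microvessel
    networks imaged as stacks of 2D ultrasound-derived microvasculature
    maps. Assembles anisotropic 3D volumes from ordered slices, extracts a
    one-voxel-wide centerline by topology-preserving thinning, organizes it
    into a graph of endpoints, branch points and vessel segments with
    distance-transform radii, and computes twelve morphological biomarkers
    (vessel density, diameter, tortuosity, Murray's deviation, bifurcation
    angle, box-counting fractal dimension, branch and segment counts) in 2D
    or 3D mode. Includes synthetic vascular phantom generators with analytic
    ground truth, and a statistical layer with Wilcoxon group comparisons, a
    leave-one-out cross-validated logistic malignancy-probability model, ROC
    analysis with DeLong confidence intervals and paired tests, and
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    RNifti,
    tiff,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
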