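---
title: "Quantifying 3D microvascular morphology with vesselmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D microvascular morphology with vesselmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The problem

Tumor angiogenesis produces microvessel networks that are denser, more
tortuous and more richly branched than the vasculature of benign masses.
Contrast-free ultrasound microvasculature imaging yields, per acquisition,
an ordered stack of 2D microvessel maps swept across a lesion at a fixed
elevational step (typically 0.5 mm, with ~0.1 mm in-plane pixels).
`vesselmorph` turns such a stack into a 3D vessel-network description and a
panel of twelve morphological biomarkers, and evaluates how well those
biomarkers separate malignant from benign lesions with a cross-validated
logistic model. A single-plane (2D) analysis mode applies the same
machinery to the slice with the largest lesion cross-section, which is the
natural baseline for judging what the volumetric analysis adds.

## The processing model

The chain is: binarize (if the input is an intensity map) -> restrict to
the analysis region (lesion mask dilated by a peritumoral margin, 2--5 mm
depending on mass size) -> topology-preserving thinning to a one-voxel
centerline -> skeleton graph (endpoints, branch points, vessel segments,
per-point radii) -> biomarkers.

Three numerical choices matter and are worth stating precisely.

**Thinning.** The centerline is extracted by sequential homotopic thinning:
a voxel is deleted only if it is *simple* — its removal preserves local
foreground and background topology under (26, 6)-connectivity in 3D and
(8, 4) in 2D — and not a curve endpoint. Deletions are organized in
six directional border sub-sweeps (four in 2D); each sweep snapshots the
current border so erosion proceeds one layer per sweep from every side,
and within a sweep voxels are visited in order of increasing distance to
the background (physical distance, so anisotropic stacks thin toward the
physically medial curve). This keeps the skeleton centered and prevents
elongated ridges from being consumed lengthwise. Thinning runs on the
native voxel grid; no resampling is done at any point, and all lengths,
angles and radii are computed in millimetres using the per-axis spacing.

**Graph construction.** Skeleton voxels with three or more neighbors are
branch voxels; adjacent branch voxels merge into a single branch node, and
two branch nodes joined by a segment shorter than the local junction
radius are merged further, since thinning a thick bifurcation often
splits one anatomical branch point into two voxels a couple of steps
apart. Spurs shorter than `prune_len` (default three voxel diagonals,
`3 * sqrt(sum(spacing^2))`) are removed iteratively to a fixed point, and
components below `min_component = 5` skeleton voxels are dropped; both are
exposed in `prune_config()` and recorded in the graph's provenance,
because thinning noise handling is an engineering choice, not something
the imaging physics dictates. A closed vessel loop with no branch point
becomes a single cyclic segment anchored at a `"loop"` node: it counts as
one segment and zero branch points.

**Arc lengths and directions.** Raw voxel chains overestimate the length
of oblique curves by up to ~8% (the digital staircase), which would alias
directly into tortuosity. Segment coordinates are therefore smoothed with
a one-voxel Gaussian (endpoints pinned) before lengths and directions are
measured; at vessel scale (curvature radii of millimetres) the smoothing
bias is negligible (<0.1%), while the staircase bias disappears.
`smooth_sigma_vox = 0` restores raw chains for anyone who wants them.
Optionally (`extend_ends`), terminal segments are extended along their end
tangent while the local caliber stays above 0.9 of the tip caliber: this
recovers centerline eroded at flat-truncated vessel ends (e.g. at the
volume border) without overshooting into rounded vessel ends, where the
thinned tip already sits at the end of the medial axis.

## The twelve biomarkers

| Parameter | Definition here |
|---|---|
| VD | vessel voxels / analysis-region voxels (pixels on the selected slice in 2D mode: per unit area vs per unit volume) |
| D_mean, D_max (mm) | per-point diameter = twice the Euclidean distance transform at the centerline, pooled over all segment points |
| tau_mean, tau_max | per-segment distance metric: arc length / endpoint chord; segments with chord below one voxel (and loops) excluded |
| MD_mean, MD_max | per-branch deviation from Murray's cube law, `abs(d_p^k - sum(d_i^k)) / d_p^k`, exponent `k = 3` by default |
| BA_mean, BA_max (deg) | angle between the two daughter directions, each fitted by least squares over the first 1 mm of daughter centerline beyond one junction radius |
| mvFD | box-counting dimension of the skeleton |
| NB, NV | branch-point and segment counts after pruning |

Decisions taken where the field's conventions leave room:

* **Parent/daughter assignment.** At each branch node the incident segment
  with the largest representative diameter is the parent; ties go to the
  longer segment, then the lowest index. Representative diameters are
  measured over a 1 mm window starting one junction radius away from the
  node, because voxels inside the junction see both vessels and
  overestimate caliber.
* **Small-vessel diameter bias.** For a one-voxel-wide vessel the distance
  transform reports one voxel, so `2 * EDT` floors at about two voxels.
  This bias is asserted in the tests rather than corrected, since any
  correction would need an orientation model the data does not provide.
* **The NaN convention.** When a network has no branch points, MD and BA
  are undefined and reported as missing — never zero. Cohort-level
  Wilcoxon comparisons then use the lesions where a parameter is defined;
  the default six-feature model panel (VD, mvFD, tau_max, NV, NB, D_mean)
  avoids branch-dependent parameters entirely, and the
  `missing = "impute-neutral"` option substitutes no-vessel neutral values
  (0 for densities and counts, 1 for tortuosity) for lesions whose
  single-plane analysis finds no usable skeleton.
* **Box ladder for mvFD.** Box sizes are powers of two from 2 voxels up to
  a quarter of the *largest* grid extent, requiring at least four sizes.
  Tying the ladder to the smallest extent would make mvFD undefined on
  shallow elevational stacks (a 121 x 121 x 17 volume would allow only two
  sizes); with the largest extent, boxes wider than a short axis simply
  span it. mvFD is computed on the skeleton by default (`fd_source`
  switches to the filled mask).
* **Tortuosity pooling.** tau is per segment (not per root-to-leaf path);
  D pools per centerline point. Both choices are logged in provenance.

Diameters in this package are millimetres throughout. Summary tables
elsewhere sometimes print sub-millimetre vessel diameters with an `mm`
label that is plainly micrometres; `vesselmorph` does not replicate that
unit slip.

## Synthetic phantoms as ground truth

No patient data ship with the package; every quantitative claim is tested
against synthetic phantoms with analytic truth:

* **Tubes** (`make_tube`): straight, circular-arc or sinusoidal
  centerlines of constant radius. Rasterization marks every voxel whose
  centre lies within the radius of the centerline, sampled at a quarter
  voxel; the result is a union of balls, so the analytic volume is the
  spherocylinder (tube plus hemispherical caps) and the analytic
  tortuosity is the arc/chord ratio (`pi/2` for a half circle).
* **Trees** (`make_tree`): binary trees of straight, per-segment-tapered
  cylinders. Daughter calibers follow `d_p^k = d_1^k + d_2^k` for a
  configured exponent (Murray deviation 0 by construction) or a fixed
  daughter/parent ratio (ratio 1 gives deviation exactly 1); the full
  daughter-daughter angle is prescribed. Self-intersecting configurations
  are rejected.
* **Cohorts** (`make_cohort`): labeled sets of lesions, each a bundle of
  vessels inside an ellipsoidal lesion mask on the default
  (0.1, 0.1, 0.5) mm grid. Geometry parameters are drawn log-normally with
  per-class medians; the malignant class has more vessels, more and deeper
  trees, and high-amplitude sinusoids, so it stochastically dominates the
  benign class on VD, NB, NV, tau and mvFD by construction — the effect
  directions reported for malignant neovasculature. The class
  configurations are free parameters chosen to exercise the pipeline with
  clear separation; they are not calibrated to any clinical dataset.

What the phantoms do *not* emulate: speckle and acoustic noise, clutter
residue, flow dropouts, motion between slices, and true vascular
branching statistics. At the default 0.5 mm elevational step the smallest
rasterizable tube radius is one voxel (0.5 mm), so cohort phantom vessels
are of millimetre caliber and phantom vessel densities (~0.02--0.15 of
the lesion region) sit far above clinical microvasculature values.
Passing the cohort-level tests therefore shows that the pipeline
preserves and detects *configured* morphological contrasts end to end; it
says nothing about effect sizes in real lesions. Fixtures used for
caliber-sensitive recovery checks (Murray deviation) are rasterized at
0.05 mm isotropic, since a representative diameter needs roughly twelve
voxels across a vessel before the half-voxel distance-transform
quantization stops dominating the cube-law ratio; topology counts and
angle sweeps are tested at 0.1 mm.

## The statistical layer

Group comparisons use the Wilcoxon rank-sum test, exact (enumerated) when
the combined sample is at most 12 without ties and the tie- and
continuity-corrected normal approximation otherwise; two-sided p < 0.05
is called significant, with no multiplicity correction across the
biomarker panel (reported as such, by design).

The malignancy model is multivariable logistic regression,
`malignancy probability = logit^-1(B + sum_i C_i P_i)`, fitted by IRLS on
z-scored features with coefficients reported on the original scale. If
separation is detected the fit is repeated with a small ridge penalty
(1e-4 on standardized features) and flagged. Honest performance comes
from leave-one-out cross-validation: each lesion is predicted by a model
trained on the others, and one ROC curve is built from the n pooled
held-out probabilities (not per-fold averaging). The reported (B, C_i)
come from the full-data fit; LOOCV supplies the probabilities and the
ROC. AUC uses the Mann-Whitney pair-counting identity with tied pairs
counting one half; its 95% interval is the DeLong Wald interval clipped
to [0, 1] (no logit transform — a choice, flagged here). The optimal
cut-point is the ROC point closest to (0, 1), ties resolved toward higher
specificity, and the confusion metrics at that cut-point include the
negative likelihood ratio `(1 - sensitivity) / specificity`. Paired model
comparison uses DeLong's test on the placement-value covariance; two
identical rankings give a zero-variance difference and p = 1 by
convention.

The package's own ROC/AUC/DeLong implementation is cross-checked in the
test suite against brute-force pair enumeration, a 20,000-replicate
stratified bootstrap, and the `pROC` package.

## Problem sizes and determinism

All simulations take explicit seeds and are bit-reproducible for a fixed
seed. The shipped tests and the acceptance script use desk-scale problem
sizes: single-phantom checks on grids of roughly 10^5--10^6 voxels,
a 93-lesion synthetic cohort (57 benign / 36 malignant, mirroring the
clinical class balance) for the end-to-end discrimination check, 100
label-shuffled replicates for the null calibration, and n = 2000 for
logistic parameter recovery. On one CPU the whole suite runs in a few
minutes.

## Known limitations

* Binary input only: vessel segmentation/enhancement upstream of the
  binarized microvessel map is out of scope.
* No inter-slice registration or motion correction; slices are assumed
  co-registered.
* Diameters near one voxel carry the documented +1-voxel bias; on the
  default anisotropic grid that is 0.5 mm elevationally.
* The cohort generator's effect sizes are synthetic; AUCs obtained on
  phantom cohorts characterize the pipeline, not any imaging modality.

## A worked example

```{r example, eval = FALSE}
library(vesselmorph)

# a Y-shaped vessel with a 90-degree bifurcation, Murray-law calibers
ph <- make_tree(centerline_spec("tree", length = 8, radius = 0.4,
                                depth = 1, daughter_angle = 90,
                                spacing = c(0.1, 0.1, 0.1)))
graph <- vessel_graph(ph$volume, prune = prune_config(extend_ends = TRUE))
count_stats(graph)             # nb = 1, nv = 3
bifurcation_angle_stats(graph) # ~90 degrees
murray_deviation_stats(graph)  # ~0

# a synthetic cohort, quantified in 3D and 2D mode
cohort <- make_cohort(57, 36, seed = 20220930)
tab3 <- quantify_cohort(cohort, mode = "3D")
a3 <- analyze_cohort(tab3, missing = "impute-neutral")
a3$roc   # pooled-LOOCV AUC, DeLong CI, optimal cut-point, confusion metrics
```
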