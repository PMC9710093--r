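#' The twelve microvessel morphology biomarkers
#'
#' Container for one lesion's quantitative vessel-morphology parameters:
#' vessel density (`vd`), mean/max vessel diameter (`d_mean`, `d_max`, mm),
#' mean/max tortuosity (`tau_mean`, `tau_max`), mean/max Murray's deviation
#' (`md_mean`, `md_max`), mean/max bifurcation angle (`ba_mean`, `ba_max`,
#' degrees), microvessel fractal dimension (`mvfd`), number of branch
#' points (`nb`) and number of vessel segments (`nv`). The `mean`/`max`
#' pairs follow the convention that the subscripted variants are the mean
#' and maximum of the underlying per-point or per-branch values. When the
#' network has no branch points the branch-dependent parameters
#' (`md_*`, `ba_*`) are undefined and reported as `NA` (the NaN
#' convention), never as zero.
#'
#' @param ... named biomarker values.
#' @param mode `"2D"` or `"3D"`.
#' @param missing character vector of reasons for missing values.
#' @return list of class `biomarker_set`.
#' @export
biomarker_set <- function(..., mode = "3D", missing = character(0)) {
  vals <- list(vd = NA_real_, d_mean = NA_real_, d_max = NA_real_,
               tau_mean = NA_real_, tau_max = NA_real_,
               md_mean = NA_real_, md_max = NA_real_,
               ba_mean = NA_real_, ba_max = NA_real_,
               mvfd = NA_real_, nb = NA_integer_, nv = NA_integer_)
  dots <- list(...)
  vals[names(dots)] <- dots
  structure(c(vals, list(mode = mode)),
            class = "biomarker_set", missing = missing)
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> (%s mode)\n", x$mode))
  fmt <- function(v) if (is.na(v)) "NA" else format(signif(v, 4))
  cat(sprintf("  VD %s | D %s/%s mm | tau %s/%s | MD %s/%s | BA %s/%s deg\n",
              fmt(x$vd), fmt(x$d_mean), fmt(x$d_max), fmt(x$tau_mean),
              fmt(x$tau_max), fmt(x$md_mean), fmt(x$md_max), fmt(x$ba_mean),
              fmt(x$ba_max)))
  cat(sprintf("  mvFD %s | NB %s | NV %s\n", fmt(x$mvfd), fmt(x$nb),
              fmt(x$nv)))
  mr <- attr(x, "missing")
  if (length(mr)) cat("  missing:", paste(mr, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  as.data.frame(x[c("vd", "d_mean", "d_max", "tau_mean", "tau_max",
                    "md_mean", "md_max", "ba_mean", "ba_max", "mvfd",
                    "nb", "nv", "mode")], stringsAsFactors = FALSE)
}

as_mask_array <- function(x) {
  if (inherits(x, "voxel_volume")) {
    if (!x$binary) stop("expected a binary volume")
    x$data
  } else if (is.logical(x)) {
    if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  } else stop("expected a binary voxel_volume or logical array")
}

#' Vessel density
#'
#' Proportion of the analysis region occupied by vessel signal: vessel
#' pixels over region pixels on a single plane in 2D mode, vessel voxels
#' over region voxels in 3D mode (per unit area vs per unit volume).
#'
#' @param vessel binary vessel mask ([voxel_volume()] or logical array).
#' @param roi analysis-region mask, congruent with `vessel`.
#' @param mode `"2D"` or `"3D"` (recorded; the computation is the count
#'   ratio over the supplied grids in either mode).
#' @return fraction in `[0, 1]`.
#' @export
vessel_density <- function(vessel, roi, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  v <- as_mask_array(vessel)
  r <- as_mask_array(roi)
  if (!identical(dim(v), dim(r))) stop("vessel and roi masks not congruent")
  if (!any(r)) stop("empty analysis region")
  sum(v & r) / sum(r)
}

#' Vessel diameter statistics
#'
#' Pools the per-point diameters (twice the centerline distance-transform
#' radius) over all segment centerline points and reports their mean and
#' maximum.
#'
#' @param graph a `skeleton_graph`.
#' @return named numeric `c(d_mean, d_max)` (mm), `NA` for an empty graph.
#' @export
diameter_stats <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  d <- unlist(lapply(graph$segments, function(s) 2 * s$radius))
  if (!length(d)) return(c(d_mean = NA_real_, d_max = NA_real_))
  c(d_mean = mean(d), d_max = max(d))
}

#' Tortuosity statistics (distance metric)
#'
#' Per-segment tortuosity is the distance metric: centerline arc length
#' divided by the straight-line distance between the segment endpoints
#' (1 for a straight vessel). Segments with chord shorter than about one
#' voxel (including closed loops) are excluded. Means and maxima are taken
#' over the included segments.
#'
#' @param graph a `skeleton_graph`.
#' @param min_chord_mm exclusion threshold; default one voxel
#'   (`max(spacing)`).
#' @return named numeric `c(tau_mean, tau_max)`; `NA` when no segment
#'   qualifies.
#' @export
tortuosity_stats <- function(graph, min_chord_mm = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (is.null(min_chord_mm))
    min_chord_mm <- max(graph$spacing[1:(if (graph$two_d) 2 else 3)])
  tau <- vapply(graph$segments, function(s)
    if (s$chord_length >= min_chord_mm) s$arc_length / s$chord_length
    else NA_real_, 0)
  tau <- tau[!is.na(tau)]
  if (!length(tau)) return(c(tau_mean = NA_real_, tau_max = NA_real_))
  c(tau_mean = mean(tau), tau_max = max(tau))
}

# Representative diameter of each segment incident to a branch node, and
# parent/daughter assignment. The representative diameter is the mean
# 2*radius over the window [excl, excl + window_mm] of arc length from the
# node, where excl is the local junction radius (junction voxels see both
# vessels and would inflate the estimate). Parent = incident segment of
# largest representative diameter; ties go to the longer segment, then the
# lower segment index.
branch_assignments <- function(graph, window_mm = 1.0) {
  branches <- which(graph$nodes$kind == "branch")
  lapply(branches, function(nid) {
    inc <- which(vapply(graph$segments, function(s) any(s$nodes == nid),
                        TRUE))
    info <- lapply(inc, function(si) {
      s <- graph$segments[[si]]
      pts <- s$points
      rad <- s$radius
      if (s$nodes[1] != nid) { # orient node end first
        pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
        rad <- rev(rad)
      }
      arc <- c(0, cumsum(sqrt(rowSums(
        (pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))))
      excl <- rad[1]
      sel <- arc >= excl & arc <= excl + window_mm
      if (!any(sel)) sel <- arc >= excl
      if (!any(sel)) sel <- rep(TRUE, length(arc))
      list(seg = si, diam = 2 * mean(rad[sel]), len = s$arc_length,
           points = pts, arc = arc, excl = excl)
    })
    diams <- vapply(info, function(i) i$diam, 0)
    lens <- vapply(info, function(i) i$len, 0)
    parent <- order(-diams, -lens, inc)[1]
    list(node = nid, segments = inc, info = info, parent = parent)
  })
}

#' Murray's deviation statistics
#'
#' At each branch node the incident segment of largest caliber is taken as
#' the parent and the remaining segments as daughters; the deviation from
#' Murray's cube law is `|d_p^k - sum(d_i^k)| / d_p^k` with exponent
#' `k = 3` by default, using representative diameters measured just beyond
#' the junction. Undefined (`NA`) when the network has no branch points.
#'
#' @param graph a `skeleton_graph`.
#' @param exponent branching-law exponent (Murray's law: 3).
#' @param window_mm diameter measurement window beyond the junction, mm.
#' @return named numeric `c(md_mean, md_max)`.
#' @export
murray_deviation_stats <- function(graph, exponent = 3, window_mm = 1.0) {
  stopifnot(inherits(graph, "skeleton_graph"))
  ba <- branch_assignments(graph, window_mm)
  if (!length(ba)) return(c(md_mean = NA_real_, md_max = NA_real_))
  md <- vapply(ba, function(b) {
    diams <- vapply(b$info, function(i) i$diam, 0)
    dp <- diams[b$parent]
    dd <- diams[-b$parent]
    abs(dp^exponent - sum(dd^exponent)) / dp^exponent
  }, 0)
  c(md_mean = mean(md), md_max = max(md))
}

#' Bifurcation angle statistics
#'
#' The bifurcation angle at a branch node is the angle between the two
#' daughter vessels: each daughter's direction is a least-squares line fit
#' over its first `fit_mm` of centerline leaving the node (single-voxel
#' direction estimates are noise-dominated on coarse elevational grids).
#' With more than two daughters the largest-caliber pair is used. Branches
#' whose daughters are too short for a fit are skipped with a warning.
#' Undefined (`NA`) when the network has no branch points.
#'
#' @param graph a `skeleton_graph`.
#' @param fit_mm direction-fit length, mm.
#' @param window_mm diameter window for parent/daughter assignment, mm.
#' @return named numeric `c(ba_mean, ba_max)` in degrees.
#' @export
bifurcation_angle_stats <- function(graph, fit_mm = 1.0, window_mm = 1.0) {
  stopifnot(inherits(graph, "skeleton_graph"))
  ba <- branch_assignments(graph, window_mm)
  if (!length(ba)) return(c(ba_mean = NA_real_, ba_max = NA_real_))
  angles <- numeric(0)
  skipped <- 0L
  for (b in ba) {
    dinfo <- b$info[-b$parent]
    if (length(dinfo) > 2) {
      dd <- vapply(dinfo, function(i) i$diam, 0)
      dinfo <- dinfo[order(-dd)[1:2]]
    }
    if (length(dinfo) < 2) { skipped <- skipped + 1L; next }
    dirs <- lapply(dinfo, function(i) {
      # skip the junction-proximal part of the daughter: within one
      # junction radius of the node the centerline still bends away from
      # the merged medial line and would bias the direction
      excl <- i$excl
      sel <- i$arc >= excl & i$arc <= excl + fit_mm
      if (sum(sel) < 2) sel <- i$arc <= excl + fit_mm
      pts <- i$points[sel, , drop = FALSE]
      if (nrow(pts) < 2) return(NULL)
      ctr <- colMeans(pts)
      pc <- stats::prcomp(pts, center = TRUE)
      v <- pc$rotation[, 1]
      away <- pts[nrow(pts), ] - i$points[1, ]
      if (sum(v * away) < 0) v <- -v
      v
    })
    if (any(vapply(dirs, is.null, TRUE))) { skipped <- skipped + 1L; next }
    cosang <- sum(dirs[[1]] * dirs[[2]]) /
      (sqrt(sum(dirs[[1]]^2)) * sqrt(sum(dirs[[2]]^2)))
    angles <- c(angles, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  if (skipped > 0L)
    warning(skipped, " branch(es) skipped: daughters too short for a ",
            "direction fit")
  if (!length(angles)) return(c(ba_mean = NA_real_, ba_max = NA_real_))
  c(ba_mean = mean(angles), ba_max = max(angles))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes over a geometric ladder of box sizes (powers of 2
#' from 2 voxels up to a quarter of the largest grid extent) and reports
#' the negative slope of the least-squares fit of `log N(s)` against
#' `log s`. Computed on the skeleton by default (the skeleton image is the
#' basis of the quantitative parameters); the structure must support at
#' least 4 ladder sizes, otherwise the value is missing with a reason.
#'
#' @param x binary [voxel_volume()] or logical array (skeleton or mask).
#' @param mode `"2D"` or `"3D"`; in 2D, boxes are squares on the slice.
#' @return `mvfd` (unitless), or `NA` with a `"reason"` attribute.
#' @export
fractal_dimension <- function(x, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  arr <- as_mask_array(x)
  dims <- dim(arr)
  idx <- which(arr)
  if (!length(idx)) {
    out <- NA_real_; attr(out, "reason") <- "empty structure"
    return(out)
  }
  coords <- arrayInd(idx, dims) - 1L
  nax <- if (mode == "2D") 2L else 3L
  coords <- coords[, seq_len(nax), drop = FALSE]
  smax <- max(dims[seq_len(nax)]) / 4
  sizes <- 2^(seq_len(32)); sizes <- sizes[sizes <= smax]
  if (length(sizes) < 4L) {
    out <- NA_real_
    attr(out, "reason") <- "structure too small for >= 4 box sizes"
    return(out)
  }
  counts <- vapply(sizes, function(s) {
    boxes <- coords %/% as.integer(s)
    nrow(unique(boxes))
  }, 0L)
  fit <- stats::lm(log(counts) ~ log(sizes))
  -unname(stats::coef(fit)[2])
}

#' Branch-point and segment counts
#'
#' `nb` is the number of branch nodes (nodes connected to three or more
#' vessel segments, after merging adjacent branch voxels), `nv` the number
#' of vessel segments after pruning.
#'
#' @param graph a `skeleton_graph`.
#' @return named integer `c(nb, nv)`.
#' @export
count_stats <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  c(nb = sum(graph$nodes$kind == "branch"), nv = length(graph$segments))
}

#' Quantification configuration
#'
#' @param dilate_mm peritumoral dilation margin applied to the lesion mask
#'   (typically 2--5 mm depending on mass size; 0 for phantoms).
#' @param binarize_method,threshold see [binarize()].
#' @param prune a [prune_config()].
#' @param murray_exponent branching-law exponent for Murray's deviation.
#' @param angle_fit_mm direction-fit length for bifurcation angles, mm.
#' @param md_window_mm diameter window beyond junctions, mm.
#' @param fd_source `"skeleton"` (default) or `"mask"` for the fractal
#'   dimension input.
#' @return list of class `quantify_config`.
#' @export
quantify_config <- function(dilate_mm = 0, binarize_method = "fixed",
                            threshold = 0, prune = prune_config(),
                            murray_exponent = 3, angle_fit_mm = 1.0,
                            md_window_mm = 1.0,
                            fd_source = c("skeleton", "mask")) {
  structure(list(dilate_mm = dilate_mm, binarize_method = binarize_method,
                 threshold = threshold, prune = prune,
                 murray_exponent = murray_exponent,
                 angle_fit_mm = angle_fit_mm, md_window_mm = md_window_mm,
                 fd_source = match.arg(fd_source)),
            class = "quantify_config")
}

#' Quantify microvessel morphology of one lesion
#'
#' Runs the full chain: binarization (if needed), peritumoral lesion-mask
#' dilation, restriction of the vessel signal to the analysis region,
#' thinning, graph construction, and all twelve biomarkers. In 2D mode the
#' computation uses the single slice with the largest lesion cross-section
#' (lowest index on ties); in 3D mode the whole volume. An empty vessel
#' mask yields a `biomarker_set` of zeros/missing values with reasons, not
#' an error.
#'
#' @param volume [voxel_volume()], binary or intensity.
#' @param mask optional lesion mask ([voxel_volume()]); when absent the
#'   whole volume is the analysis region.
#' @param mode `"3D"` or `"2D"`.
#' @param config a [quantify_config()].
#' @return a [biomarker_set()] with a `provenance` attribute recording the
#'   resolved parameters.
#' @export
quantify <- function(volume, mask = NULL, mode = c("3D", "2D"),
                     config = quantify_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(config, "quantify_config"))
  if (!volume$binary)
    volume <- binarize(volume, config$binarize_method, config$threshold)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_volume"))
    if (!identical(dim(mask$data), dim(volume$data)))
      stop("lesion mask not congruent with volume")
    roi <- dilate_mask(mask, config$dilate_mm)
  } else {
    roi <- voxel_volume(array(TRUE, dim(volume$data)), volume$spacing,
                        volume$origin, volume$mode)
  }
  if (mode == "2D" && dim(volume$data)[3] > 1L) {
    k <- if (!is.null(mask)) largest_lesion_slice(mask)
         else which.max(apply(volume$data, 3, sum))
    volume <- volume_slice(volume, k)
    roi <- volume_slice(roi, k)
  }
  vessels <- voxel_volume(volume$data & roi$data, volume$spacing,
                          volume$origin, volume$mode)
  vd <- vessel_density(vessels, roi, mode)
  if (!any(vessels$data)) {
    return(biomarker_set(vd = 0, nb = 0L, nv = 0L, mode = mode,
                         missing = "no vessel signal in the analysis region"))
  }
  dt <- distance_transform(vessels)
  skel <- extract_skeleton(vessels)
  graph <- build_graph(skel, dt, prune = config$prune)
  cs <- count_stats(graph)
  miss <- character(0)
  if (cs["nv"] == 0) {
    return(biomarker_set(vd = vd, nb = 0L, nv = 0L, mode = mode,
                         missing = "skeleton empty after pruning"))
  }
  ds <- diameter_stats(graph)
  ts <- tortuosity_stats(graph)
  if (cs["nb"] > 0) {
    ms <- murray_deviation_stats(graph, config$murray_exponent,
                                 config$md_window_mm)
    bs <- suppressWarnings(
      bifurcation_angle_stats(graph, config$angle_fit_mm,
                              config$md_window_mm))
  } else {
    ms <- c(md_mean = NA_real_, md_max = NA_real_)
    bs <- c(ba_mean = NA_real_, ba_max = NA_real_)
    miss <- c(miss, "no branch points: MD and BA undefined")
  }
  fd_input <- if (config$fd_source == "skeleton")
    voxel_volume(array(graph$skeleton, dim(vessels$data)), vessels$spacing,
                 vessels$origin, vessels$mode) else vessels
  fd <- fractal_dimension(fd_input, mode)
  if (is.na(fd)) miss <- c(miss, paste("mvFD:", attr(fd, "reason")))
  out <- biomarker_set(
    vd = vd, d_mean = unname(ds["d_mean"]), d_max = unname(ds["d_max"]),
    tau_mean = unname(ts["tau_mean"]), tau_max = unname(ts["tau_max"]),
    md_mean = unname(ms["md_mean"]), md_max = unname(ms["md_max"]),
    ba_mean = unname(bs["ba_mean"]), ba_max = unname(bs["ba_max"]),
    mvfd = as.numeric(fd), nb = unname(as.integer(cs["nb"])),
    nv = unname(as.integer(cs["nv"])), mode = mode, missing = miss)
  attr(out, "provenance") <- list(config = config,
                                  prune = graph$provenance,
                                  spacing = volume$spacing)
  out
}

#' Quantify every lesion of a cohort
#'
#' Applies [quantify()] to each lesion of a [make_cohort()] result (or any
#' list with `volume`, `mask`, `label`) and assembles the feature table.
#'
#' @param cohort list of lesions.
#' @param mode `"3D"` or `"2D"`.
#' @param config a [quantify_config()].
#' @return data frame with one row per lesion: the twelve biomarkers plus
#'   `label` and `lesion`.
#' @export
quantify_cohort <- function(cohort, mode = c("3D", "2D"),
                            config = quantify_config()) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(cohort), function(i) {
    les <- cohort[[i]]
    bm <- quantify(les$volume, les$mask, mode = mode, config = config)
    df <- as.data.frame(bm)
    df$label <- les$label
    df$lesion <- i
    df
  })
  do.call(rbind, rows)
}
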