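#' Specify a synthetic vessel centerline
#'
#' Describes an analytic centerline (straight, circular arc, sinusoid, or a
#' bifurcating tree of straight tapering segments) together with the voxel
#' spacing it will be rasterized on. Lengths are mm, angles in the stated
#' units. The default spacing mimics a mechanically swept linear-array
#' acquisition: 0.1 mm in plane with 0.5 mm elevational steps.
#'
#' @param kind one of `"straight"`, `"arc"`, `"sinusoid"`, `"tree"`.
#' @param length centerline length mm (for `sinusoid`, extent along the
#'   main axis; for `tree`, the root segment length).
#' @param radius tube radius mm (tree: root radius = parent diameter / 2).
#' @param arc_angle arc subtended angle, radians (arc only).
#' @param amplitude,period sinusoid amplitude and period, mm.
#' @param depth tree depth (number of bifurcation generations, >= 1).
#' @param murray_exponent exponent `k` in the branching law
#'   `d_p^k = d_1^k + d_2^k`; daughters are equal caliber.
#' @param daughter_scale optional override: each daughter diameter =
#'   `daughter_scale * parent diameter` (ignores `murray_exponent`), e.g. 1
#'   for an equal-caliber Y.
#' @param daughter_angle full angle between the two daughters, degrees.
#' @param length_decay child segment length ratio per generation.
#' @param azimuth_deg,elevation_deg rigid rotation applied to the phantom:
#'   in-plane rotation and out-of-plane tilt, degrees.
#' @param spacing voxel spacing mm `(axial, lateral, elevational)`.
#' @return list of class `centerline_spec`.
#' @export
centerline_spec <- function(kind = c("straight", "arc", "sinusoid", "tree"),
                            length = 20, radius = 0.5, arc_angle = pi,
                            amplitude = 1, period = 5, depth = 1,
                            murray_exponent = 3, daughter_scale = NULL,
                            daughter_angle = 90, length_decay = 0.6,
                            azimuth_deg = 0, elevation_deg = 0,
                            spacing = c(0.1, 0.1, 0.5)) {
  kind <- match.arg(kind)
  stopifnot(length > 0, radius > 0, period > 0, depth >= 1,
            daughter_angle > 0, daughter_angle < 180)
  structure(list(kind = kind, length = length, radius = radius,
                 arc_angle = arc_angle, amplitude = amplitude, period = period,
                 depth = depth, murray_exponent = murray_exponent,
                 daughter_scale = daughter_scale,
                 daughter_angle = daughter_angle, length_decay = length_decay,
                 azimuth_deg = azimuth_deg, elevation_deg = elevation_deg,
                 spacing = as.numeric(spacing)),
            class = "centerline_spec")
}

# rotation: azimuth about the elevational axis (mixes axial/lateral), then
# tilt about the axial axis (mixes lateral/elevational)
rotation_matrix <- function(azimuth_deg, elevation_deg) {
  a <- azimuth_deg * pi / 180
  e <- elevation_deg * pi / 180
  Ra <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Re <- matrix(c(1, 0, 0, 0, cos(e), sin(e), 0, -sin(e), cos(e)), 3, 3)
  Re %*% Ra
}

# analytic centerline in the canonical frame (main direction +lateral,
# curvature in the axial direction), sampled at arc step <= `step` mm
canonical_centerline <- function(spec, step) {
  L <- spec$length
  switch(spec$kind,
    straight = {
      t <- seq(0, L, by = step)
      if (t[length(t)] < L) t <- c(t, L)
      cbind(0, t, 0)
    },
    arc = {
      th <- spec$arc_angle
      stopifnot(th > 0, th <= 2 * pi)
      R <- L / th
      u <- seq(0, th, length.out = max(2L, ceiling(L / step) + 1L))
      cbind(R * (1 - cos(u)), R * sin(u), 0)
    },
    sinusoid = {
      # fine parametric sampling, then re-note: arc step bounded by param step
      t <- seq(0, L, length.out = max(2L, ceiling(4 * L / step) + 1L))
      cbind(spec$amplitude * sin(2 * pi * t / spec$period), t, 0)
    },
    stop("tree centerlines are built by make_tree()"))
}

polyline_arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

polyline_chord <- function(pts) sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))

# closed-form / high-resolution analytic tortuosity of a centerline kind
analytic_tortuosity <- function(spec) {
  switch(spec$kind,
    straight = 1,
    arc = {
      th <- spec$arc_angle
      (th / 2) / sin(th / 2)
    },
    sinusoid = {
      pts <- canonical_centerline(spec, step = spec$length / 2e5)
      polyline_arc_length(pts) / polyline_chord(pts)
    },
    1)
}

#' Rasterize tubes around sampled centerlines
#'
#' Marks every voxel whose centre lies within the tube radius of the
#' (densely sampled) centerline, measuring distance in physical units so
#' anisotropic grids are handled without artifacts. The centerline is
#' sampled at steps of at most a quarter of the smallest voxel size, so the
#' rasterized set is a union of balls indistinguishable from the exact tube
#' at voxel resolution.
#'
#' @param polylines list of n-by-3 matrices of centerline points, mm.
#' @param radii numeric vector, one tube radius (mm) per polyline.
#' @param spacing voxel spacing mm.
#' @param dims optional fixed volume dimensions; when `NULL` the volume is
#'   auto-sized to the dilated centerlines plus a margin, and the polylines
#'   are translated accordingly (the applied shift is returned).
#' @param margin_vox margin in voxels for auto-sizing.
#' @return list with `volume` (a binary [voxel_volume()]), `polylines`
#'   (possibly shifted), and `shift` (mm).
#' @export
rasterize_tubes <- function(polylines, radii, spacing, dims = NULL,
                            margin_vox = 3L) {
  stopifnot(length(polylines) == length(radii), all(radii > 0))
  if (any(radii < max(spacing)))
    stop("tube radius ", min(radii), " mm is smaller than one voxel (",
         max(spacing), " mm) along some axis; it would vanish on this grid")
  spacing <- as.numeric(spacing)
  step <- 0.25 * min(spacing)
  shift <- c(0, 0, 0)
  if (is.null(dims)) {
    all_pts <- do.call(rbind, polylines)
    rmax <- max(radii)
    lo <- apply(all_pts, 2, min) - rmax - margin_vox * spacing
    hi <- apply(all_pts, 2, max) + rmax + margin_vox * spacing
    lo <- floor(lo / spacing) * spacing # keep input coordinates on-grid
    shift <- -lo
    polylines <- lapply(polylines, function(p) sweep(p, 2, lo))
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  vol <- array(FALSE, dims)
  for (v in seq_along(polylines)) {
    pts <- resample_polyline(polylines[[v]], step)
    r <- radii[v]
    noff <- ceiling(r / spacing) + 1L
    off <- as.matrix(expand.grid(i = -noff[1]:noff[1], j = -noff[2]:noff[2],
                                 k = -noff[3]:noff[3]))
    for (s in seq_len(nrow(pts))) {
      p <- pts[s, ]
      ci <- round(p / spacing) + 1L
      cand <- sweep(off, 2, ci, "+")
      keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
              cand[, 2] >= 1 & cand[, 2] <= dims[2] &
              cand[, 3] >= 1 & cand[, 3] <= dims[3]
      if (!any(keep)) next
      cand <- cand[keep, , drop = FALSE]
      ctr <- sweep(cand - 1, 2, spacing, "*")
      d2 <- (ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 + (ctr[, 3] - p[3])^2
      # closed-ball test with a relative epsilon so voxel centres lying
      # exactly on the tube surface are not lost to float rounding
      hit <- cand[d2 <= r * r * (1 + 1e-9), , drop = FALSE]
      if (nrow(hit))
        vol[hit[, 1] + dims[1] * (hit[, 2] - 1) +
            dims[1] * dims[2] * (hit[, 3] - 1)] <- TRUE
    }
  }
  list(volume = voxel_volume(vol, spacing, mode = if (dims[3] == 1L) "2D"
                             else "3D"),
       polylines = polylines, shift = shift)
}

# resample a polyline to (roughly) uniform arc step
resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(pts[1, , drop = FALSE])
  u <- seq(0, L, by = step)
  if (u[length(u)] < L) u <- c(u, L)
  cbind(stats::approx(s, pts[, 1], xout = u)$y,
        stats::approx(s, pts[, 2], xout = u)$y,
        stats::approx(s, pts[, 3], xout = u)$y)
}

phantom_truth <- function(diameters, tortuosity, angles = numeric(0),
                          murray_dev = numeric(0), nb = 0L, nv = 1L,
                          volume_fraction = NA_real_,
                          centerlines = NULL) {
  structure(list(true_diameters = diameters, true_tortuosity = tortuosity,
                 true_bifurcation_angles = angles,
                 true_murray_deviation = murray_dev,
                 true_nb = nb, true_nv = nv,
                 true_volume_fraction = volume_fraction,
                 centerlines = centerlines),
            class = "phantom_truth")
}

#' Generate a single-tube phantom with analytic truth
#'
#' Rasterizes one straight, arc or sinusoidal tube of constant radius on an
#' (optionally anisotropic) grid and returns the volume together with its
#' analytic ground truth: diameter, tortuosity (arc length over chord), and
#' the exact spherocylinder volume fraction (tube plus hemispherical caps,
#' matching the union-of-balls rasterization).
#'
#' @param spec a [centerline_spec()] with kind straight/arc/sinusoid.
#' @return list with `volume` ([voxel_volume()]) and `truth`
#'   (`phantom_truth`).
#' @export
make_tube <- function(spec) {
  stopifnot(inherits(spec, "centerline_spec"))
  if (spec$kind == "tree") stop("use make_tree() for kind = 'tree'")
  spacing <- spec$spacing
  if (spec$radius < max(spacing))
    stop("tube radius ", spec$radius, " mm is smaller than one voxel (",
         max(spacing), " mm) along some axis")
  pts <- canonical_centerline(spec, step = 0.25 * min(spacing))
  R <- rotation_matrix(spec$azimuth_deg, spec$elevation_deg)
  pts <- pts %*% t(R)
  ras <- rasterize_tubes(list(pts), spec$radius, spacing)
  arc <- polyline_arc_length(ras$polylines[[1]])
  vox_total <- prod(dim(ras$volume$data)) * prod(spacing)
  vol_mm3 <- pi * spec$radius^2 * arc + (4 / 3) * pi * spec$radius^3
  truth <- phantom_truth(
    diameters = 2 * spec$radius,
    tortuosity = analytic_tortuosity(spec),
    volume_fraction = vol_mm3 / vox_total,
    centerlines = ras$polylines)
  list(volume = ras$volume, truth = truth)
}

# straight tree segments: list of (p0, p1, radius, generation)
build_tree_segments <- function(spec, start = c(0, 0, 0), dir = c(0, 1, 0)) {
  half <- spec$daughter_angle / 2 * pi / 180
  segs <- list()
  # child diameter rule
  child_d <- function(dp) {
    if (!is.null(spec$daughter_scale)) return(rep(dp * spec$daughter_scale, 2))
    k <- spec$murray_exponent
    rep(dp * (2^(-1 / k)), 2)
  }
  recurse <- function(p0, dir, len, diam, gen) {
    p1 <- p0 + dir * len
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, radius = diam / 2,
                                       gen = gen)
    if (gen < spec$depth) {
      d2 <- child_d(diam)
      # rotate direction by +/- half the daughter angle within the
      # axial-lateral plane spanned with the current direction
      rot <- function(v, ang) {
        c(cos(ang) * v[1] - sin(ang) * v[2],
          sin(ang) * v[1] + cos(ang) * v[2], v[3])
      }
      recurse(p1, rot(dir, half), len * spec$length_decay, d2[1], gen + 1L)
      recurse(p1, rot(dir, -half), len * spec$length_decay, d2[2], gen + 1L)
    }
  }
  recurse(start, dir / sqrt(sum(dir^2)), spec$length, 2 * spec$radius, 0L)
  segs
}

# minimum distance between two 3D segments (sampled; adequate for checks)
segments_too_close <- function(a, b, clearance) {
  pa <- resample_polyline(rbind(a$p0, a$p1), clearance / 4)
  pb <- resample_polyline(rbind(b$p0, b$p1), clearance / 4)
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
          (pb[, 3] - pa[i, 3])^2
    if (any(d2 < clearance^2)) return(TRUE)
  }
  FALSE
}

#' Generate a bifurcating-tree phantom with analytic truth
#'
#' Builds a binary tree of straight cylindrical segments. At each branch
#' point the two (equal-caliber) daughters satisfy the branching law
#' `d_p^k = d_1^k + d_2^k` for the configured exponent, or a fixed
#' `daughter_scale`; the full angle between the daughters is prescribed.
#' Taper is applied per segment so the ground truth stays exact. The truth
#' records, per branch point, the deviation from Murray's cube law
#' `|d_p^3 - sum(d_i^3)| / d_p^3` evaluated on the configured diameters.
#'
#' @param spec a [centerline_spec()] with `kind = "tree"`.
#' @return list with `volume` and `truth` as in [make_tube()].
#' @export
make_tree <- function(spec) {
  stopifnot(inherits(spec, "centerline_spec"), spec$kind == "tree")
  spacing <- spec$spacing
  segs <- build_tree_segments(spec)
  R <- rotation_matrix(spec$azimuth_deg, spec$elevation_deg)
  segs <- lapply(segs, function(s) {
    s$p0 <- as.vector(R %*% s$p0); s$p1 <- as.vector(R %*% s$p1); s
  })
  radii <- vapply(segs, function(s) s$radius, 0)
  if (any(radii < max(spacing)))
    stop("tree daughter radius ", min(radii),
         " mm is smaller than one voxel along some axis; reduce depth or ",
         "increase the root radius")
  # reject geometric self-intersection between non-adjacent segments
  n <- length(segs)
  if (n > 3) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      share <- any(apply(rbind(segs[[i]]$p0, segs[[i]]$p1), 1, function(p)
        min(sum((p - segs[[j]]$p0)^2), sum((p - segs[[j]]$p1)^2)) < 1e-12))
      if (!share &&
          segments_too_close(segs[[i]], segs[[j]],
                             segs[[i]]$radius + segs[[j]]$radius))
        stop("tree configuration is geometrically self-intersecting")
    }
  }
  polylines <- lapply(segs, function(s) rbind(s$p0, s$p1))
  ras <- rasterize_tubes(polylines, radii, spacing)
  nb <- as.integer(2^spec$depth - 1)
  nv <- as.integer(2^(spec$depth + 1) - 1)
  diams <- 2 * radii
  # per-branch Murray deviation under the cube-law formula on true
  # diameters; branch b (1-based, breadth-first) has its parent segment in
  # generation floor(log2(b))
  gens <- vapply(segs, function(s) s$gen, 0L)
  md <- vapply(seq_len(nb), function(b) {
    gen <- floor(log2(b))
    dp <- diams[match(gen, gens)]
    dd <- diams[match(gen + 1L, gens)]
    abs(dp^3 - 2 * dd^3) / dp^3
  }, 0)
  truth <- phantom_truth(
    diameters = diams, tortuosity = rep(1, nv),
    angles = rep(spec$daughter_angle, nb), murray_dev = md,
    nb = nb, nv = nv,
    volume_fraction = sum(pi * radii^2 *
                            vapply(segs, function(s)
                              sqrt(sum((s$p1 - s$p0)^2)), 0)) /
      (prod(dim(ras$volume$data)) * prod(spacing)),
    centerlines = ras$polylines)
  list(volume = ras$volume, truth = truth)
}

#' Default effect configuration for synthetic cohorts
#'
#' Per-class distributions of phantom geometry parameters. Geometry
#' parameters are drawn log-normally (they are positive scales); the
#' medians below encode the malignant phenotype reported for tumor
#' neovasculature: denser, more tortuous and more branched networks, i.e.
#' malignant lesions stochastically dominate benign ones on vessel density,
#' branch and segment counts, tortuosity and fractal dimension, while
#' vessel caliber stays comparable.
#'
#' @param benign,malignant named lists overriding individual entries.
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(benign = list(), malignant = list()) {
  base_b <- list(n_vessels = 2, n_sdlog = 0.3,
                 diameter = 0.45, diameter_sdlog = 0.12,
                 length = 7, length_sdlog = 0.2,
                 tree_prob = 0.03, tree_depth_max = 1,
                 sin_prob = 0.15, amplitude = 0.15, amplitude_sdlog = 0.3,
                 period = 6)
  base_m <- list(n_vessels = 6, n_sdlog = 0.25,
                 diameter = 0.5, diameter_sdlog = 0.12,
                 length = 8, length_sdlog = 0.2,
                 tree_prob = 0.8, tree_depth_max = 2,
                 sin_prob = 0.85, amplitude = 1.3, amplitude_sdlog = 0.25,
                 period = 3)
  base_b[names(benign)] <- benign
  base_m[names(malignant)] <- malignant
  structure(list(benign = base_b, malignant = base_m),
            class = "cohort_effects")
}

rlnorm_med <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# one random vessel (polylines + radii + bookkeeping truths)
random_vessel <- function(cfg, spacing, bounds_mm) {
  r <- max(rlnorm_med(1, cfg$diameter, cfg$diameter_sdlog) / 2,
           max(spacing))
  len <- rlnorm_med(1, cfg$length, cfg$length_sdlog)
  az <- stats::runif(1, 0, 360)
  el <- stats::rnorm(1, 0, 12) # mostly in-plane, as swept acquisitions are
  ctr <- bounds_mm * (0.5 + stats::runif(3, -0.22, 0.22))
  u <- stats::runif(1)
  if (u < cfg$tree_prob) {
    depth <- sample(seq_len(cfg$tree_depth_max), 1)
    # keep the deepest daughters at >= 1 voxel radius
    need <- max(spacing) * 2^(depth / 3)
    spec <- centerline_spec("tree", length = len * 0.5,
                            radius = max(r, need),
                            daughter_angle = stats::runif(1, 50, 110),
                            depth = depth, azimuth_deg = az,
                            elevation_deg = el, spacing = spacing)
    segs <- build_tree_segments(spec)
    R <- rotation_matrix(az, el)
    polylines <- lapply(segs, function(s)
      sweep(rbind(s$p0, s$p1) %*% t(R), 2, ctr - c(0, len * 0.25, 0), "+"))
    radii <- vapply(segs, function(s) s$radius, 0)
    nb <- 2L^depth - 1L
    nv <- 2L^(depth + 1L) - 1L
    tort <- rep(1, nv)
  } else {
    kind <- if (u < cfg$tree_prob + cfg$sin_prob) "sinusoid" else
      sample(c("straight", "arc"), 1)
    spec <- centerline_spec(kind, length = len, radius = r,
                            arc_angle = stats::runif(1, 0.3, 1.2),
                            amplitude = rlnorm_med(1, cfg$amplitude,
                                                   cfg$amplitude_sdlog),
                            period = cfg$period, azimuth_deg = az,
                            elevation_deg = el, spacing = spacing)
    pts <- canonical_centerline(spec, step = 0.25 * min(spacing))
    R <- rotation_matrix(az, el)
    pts <- pts %*% t(R)
    mid <- colMeans(pts)
    polylines <- list(sweep(pts, 2, ctr - mid, "+"))
    radii <- r
    nb <- 0L
    nv <- 1L
    tort <- analytic_tortuosity(spec)
  }
  arcs <- vapply(polylines, polyline_arc_length, 0)
  list(polylines = polylines, radii = radii, nb = nb, nv = nv,
       tortuosity = tort, volume_mm3 = sum(pi * radii^2 * arcs))
}

#' Generate a labeled cohort of vascular phantom lesions
#'
#' Draws `n_benign + n_malignant` synthetic lesions, each a set of vessels
#' (tubes, sinusoids, small trees) rasterized into an anisotropic volume
#' with an ellipsoidal lesion mask. The per-class geometry distributions
#' come from [cohort_effects()]; by construction the malignant class
#' stochastically dominates the benign class on vessel density, branch and
#' segment counts, tortuosity and fractal dimension. Fully reproducible for
#' a fixed seed.
#'
#' @param n_benign,n_malignant class sizes, each >= 2.
#' @param effects a [cohort_effects()] configuration.
#' @param seed integer seed controlling all randomness.
#' @param spacing voxel spacing mm.
#' @param size_mm physical volume extent mm (axial, lateral, elevational).
#' @return list of class `vessel_cohort`; each element has `volume`,
#'   `mask` (lesion ellipsoid), `label` (`"benign"`/`"malignant"`) and
#'   `truth` (approximate analytic summaries: true vessel volume fraction,
#'   counts, mean tortuosity).
#' @export
make_cohort <- function(n_benign, n_malignant, effects = cohort_effects(),
                        seed = 20220930, spacing = c(0.1, 0.1, 0.5),
                        size_mm = c(12, 12, 8)) {
  if (n_benign < 2 || n_malignant < 2)
    stop("need at least 2 lesions per class")
  stopifnot(inherits(effects, "cohort_effects"))
  same <- isTRUE(all.equal(effects$benign, effects$malignant))
  novar <- all(c(effects$benign$n_sdlog, effects$benign$diameter_sdlog,
                 effects$benign$length_sdlog) == 0)
  if (same && novar)
    warning("degenerate effect configuration: classes identical with zero ",
            "variance; generating anyway")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  dims <- as.integer(round(size_mm / spacing)) + 1L
  # ellipsoidal lesion mask centred in the volume
  ctr_idx <- (dims - 1) / 2
  semi <- size_mm * 0.42
  grid_i <- ((seq_len(dims[1]) - 1) - ctr_idx[1]) * spacing[1] / semi[1]
  grid_j <- ((seq_len(dims[2]) - 1) - ctr_idx[2]) * spacing[2] / semi[2]
  grid_k <- ((seq_len(dims[3]) - 1) - ctr_idx[3]) * spacing[3] / semi[3]
  mask_arr <- outer(outer(grid_i^2, grid_j^2, "+"), grid_k^2, "+") <= 1
  mask <- voxel_volume(mask_arr, spacing)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  lesions <- vector("list", length(labels))
  for (li in seq_along(labels)) {
    cfg <- effects[[labels[li]]]
    nv <- max(1L, round(rlnorm_med(1, cfg$n_vessels, cfg$n_sdlog)))
    polylines <- list(); radii <- numeric(0)
    nb_true <- 0L; nv_true <- 0L; tort <- numeric(0); volmm3 <- 0
    for (v in seq_len(nv)) {
      ves <- random_vessel(cfg, spacing, size_mm)
      polylines <- c(polylines, ves$polylines)
      radii <- c(radii, ves$radii)
      nb_true <- nb_true + ves$nb
      nv_true <- nv_true + ves$nv
      tort <- c(tort, ves$tortuosity)
      volmm3 <- volmm3 + ves$volume_mm3
    }
    ras <- rasterize_tubes(polylines, radii, spacing, dims = dims)
    lesions[[li]] <- list(
      volume = ras$volume, mask = mask, label = labels[li],
      truth = list(true_vd = volmm3 / (prod(dims) * prod(spacing)),
                   true_nb = nb_true, true_nv = nv_true,
                   true_tau_mean = mean(tort)))
  }
  structure(lesions, class = "vessel_cohort", seed = seed)
}
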