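test_that("vessel density is the occupancy fraction of the analysis region", {
  m <- array(c(TRUE, FALSE), c(10, 10, 4))
  roi <- array(TRUE, c(10, 10, 4))
  expect_identical(vessel_density(m, m), 1)
  expect_identical(vessel_density(array(FALSE, dim(m)), roi), 0)
  expect_error(vessel_density(m, array(FALSE, dim(m))), "empty")
  expect_error(vessel_density(m, array(TRUE, c(5, 5, 4))), "congruent")

  ph <- make_tube(centerline_spec("straight", length = 15, radius = 1.0,
                                  spacing = iso01))
  vd <- vessel_density(ph$volume, array(TRUE, dim(ph$volume$data)))
  expect_equal(vd, ph$truth$true_volume_fraction, tolerance = 0.02)
})

test_that("diameters pool per-point over segments", {
  g <- fix_tube()$graph
  ds <- diameter_stats(g)
  expect_equal(unname(ds["d_mean"]), 1.0, tolerance = 0.1)
  expect_equal(unname(ds["d_max"]), 1.0, tolerance = 0.1)
  expect_gte(ds["d_max"], ds["d_mean"])

  two <- rasterize_tubes(
    list(cbind(0, seq(0, 20, 0.025), 0), cbind(5, seq(0, 20, 0.025), 0)),
    radii = c(0.3, 0.6), spacing = iso01)
  g2 <- vessel_graph(two$volume, prune = pc_recover)
  ds2 <- diameter_stats(g2)
  expect_equal(unname(ds2["d_max"]), 1.2, tolerance = 0.1)
  expect_equal(unname(ds2["d_mean"]), 0.9, tolerance = 0.1)

  empty <- build_graph(
    extract_skeleton(voxel_volume(array(FALSE, c(4, 4, 2)), c(1, 1, 1))),
    array(0, c(4, 4, 2)))
  expect_true(all(is.na(diameter_stats(empty))))
})

test_that("tortuosity is the distance metric with closed-form recovery", {
  expect_equal(unname(tortuosity_stats(fix_tube()$graph)["tau_mean"]), 1.0,
               tolerance = 0.03)
  expect_equal(unname(tortuosity_stats(fix_arc()$graph)["tau_mean"]), pi / 2,
               tolerance = 0.03)

  # one straight + one half-circle segment in a single volume
  th <- seq(0, pi, length.out = 400)
  R <- 15 / pi
  both <- rasterize_tubes(
    list(cbind(0, seq(0, 15, 0.025), 0),
         cbind(4 + R * (1 - cos(th)), R * sin(th), 0)),
    radii = c(0.3, 0.3), spacing = iso01)
  gb <- vessel_graph(both$volume, prune = pc_recover)
  ts <- tortuosity_stats(gb)
  expect_equal(unname(ts["tau_max"]), pi / 2, tolerance = 0.03)
  expect_equal(unname(ts["tau_mean"]), (1 + pi / 2) / 2, tolerance = 0.03)
})

test_that("Murray deviation recovers the branching law and its violation", {
  md <- murray_deviation_stats(fix_murray_fine()$graph)
  expect_lte(unname(md["md_max"]), 0.15)

  md_eq <- murray_deviation_stats(fix_equal_y_fine()$graph)
  expect_equal(unname(md_eq["md_mean"]), 1.0, tolerance = 0.15)

  expect_true(all(is.na(murray_deviation_stats(fix_tube()$graph))))
})

test_that("bifurcation angles recover prescribed geometry", {
  ba <- bifurcation_angle_stats(fix_ytree()$graph)
  expect_equal(unname(ba["ba_mean"]), 90, tolerance = 5)

  # T junction: daughters collinear and opposite -> 180 degrees
  tj <- rasterize_tubes(
    list(cbind(5, seq(0, 14, 0.025), 1),
         cbind(seq(0, 5, 0.025), 7, 1)),
    radii = c(0.3, 0.45), spacing = iso01)
  gt <- vessel_graph(tj$volume, prune = pc_recover)
  expect_identical(unname(count_stats(gt)["nb"]), 1L)
  expect_equal(unname(bifurcation_angle_stats(gt)["ba_mean"]), 180,
               tolerance = 5)

  expect_true(all(is.na(bifurcation_angle_stats(fix_tube()$graph))))
})

test_that("bifurcation angles track a prescribed sweep within 5 degrees", {
  for (ang in c(45, 60, 120, 150)) {
    ph <- make_tree(centerline_spec("tree", length = 8, radius = 0.4,
                                    depth = 1, daughter_angle = ang,
                                    spacing = iso01))
    g <- vessel_graph(ph$volume, prune = pc_recover)
    expect_equal(unname(bifurcation_angle_stats(g)["ba_mean"]), ang,
                 tolerance = 5)
  }
})

test_that("box-counting dimension matches closed-form structures", {
  line <- array(FALSE, c(512, 512, 1)); line[256, , 1] <- TRUE
  expect_equal(fractal_dimension(line, "2D"), 1.0, tolerance = 0.1)
  square <- array(TRUE, c(256, 256, 1))
  expect_equal(fractal_dimension(square, "2D"), 2.0, tolerance = 0.1)
  cube <- array(TRUE, c(64, 64, 64))
  expect_equal(fractal_dimension(cube, "3D"), 3.0, tolerance = 0.1)

  tiny <- array(TRUE, c(3, 3, 1))
  fd <- fractal_dimension(tiny, "2D")
  expect_true(is.na(fd))
  expect_match(attr(fd, "reason"), "box sizes")
})

test_that("branch and segment counts follow graph topology", {
  expect_identical(unname(count_stats(fix_tube()$graph)), c(0L, 1L))
  expect_identical(unname(count_stats(fix_tree_depth2()$graph)), c(3L, 7L))
  expect_identical(unname(count_stats(fix_tree_depth3()$graph)), c(7L, 15L))
})

test_that("quantify runs the full chain and is deterministic", {
  fx <- fix_tube()
  qc <- quantify_config(prune = pc_recover)
  b <- quantify(fx$ph$volume, mode = "3D", config = qc)
  expect_gt(b$vd, 0)
  expect_identical(b$nb, 0L)
  expect_identical(b$nv, 1L)
  expect_equal(b$tau_mean, 1, tolerance = 0.03)
  expect_true(is.na(b$md_mean) && is.na(b$ba_mean))

  y <- fix_ytree()
  by <- quantify(y$ph$volume, mode = "3D", config = qc)
  expect_identical(by$nb, 1L)
  expect_identical(by$nv, 3L)
  expect_equal(by$ba_mean, 90, tolerance = 5)

  again <- quantify(y$ph$volume, mode = "3D", config = qc)
  expect_identical(as.data.frame(by), as.data.frame(again))
})

test_that("an empty vessel mask yields flagged zeros, not an error", {
  ev <- voxel_volume(array(FALSE, c(12, 12, 4)), c(0.1, 0.1, 0.5))
  b <- quantify(ev)
  expect_identical(b$vd, 0)
  expect_identical(b$nb, 0L)
  expect_identical(b$nv, 0L)
  expect_true(is.na(b$mvfd))
  expect_match(attr(b, "missing"), "no vessel signal")
})

test_that("max variants dominate mean variants on every paired parameter", {
  coh <- make_cohort(3, 3, seed = 17)
  tab <- quantify_cohort(coh, mode = "3D")
  for (p in c("d", "tau", "md", "ba")) {
    mn <- tab[[paste0(p, "_mean")]]
    mx <- tab[[paste0(p, "_max")]]
    ok <- !is.na(mn) & !is.na(mx)
    expect_true(all(mx[ok] >= mn[ok] - 1e-12))
  }
  # the NaN convention: branch-dependent parameters missing iff NB = 0
  expect_identical(is.na(tab$md_mean), tab$nb == 0)
  expect_identical(is.na(tab$ba_mean), tab$nb == 0)
})

test_that("tortuosity and angles are invariant under rigid rotation", {
  rot_arc <- make_tube(centerline_spec("arc", length = 15, radius = 0.3,
                                       arc_angle = pi, azimuth_deg = 30,
                                       elevation_deg = 20, spacing = iso01))
  tau <- tortuosity_stats(vessel_graph(rot_arc$volume,
                                       prune = pc_recover))["tau_mean"]
  expect_lt(abs(tau / (pi / 2) - 1), 0.05)

  rot_y <- make_tree(centerline_spec("tree", length = 8, radius = 0.4,
                                     depth = 1, daughter_angle = 90,
                                     azimuth_deg = 25, elevation_deg = 15,
                                     spacing = iso01))
  ba <- bifurcation_angle_stats(vessel_graph(rot_y$volume,
                                             prune = pc_recover))["ba_mean"]
  expect_lt(abs(ba - 90), 5)
})

test_that("isotropic physical rescaling scales diameters and fixes ratios", {
  fx <- fix_ytree()
  g1 <- fx$graph
  scaled <- voxel_volume(fx$ph$volume$data, fx$ph$volume$spacing * 2)
  g2 <- vessel_graph(scaled, prune = pc_recover)
  expect_identical(count_stats(g1), count_stats(g2))
  expect_equal(unname(diameter_stats(g2)["d_mean"]),
               2 * unname(diameter_stats(g1)["d_mean"]), tolerance = 1e-9)
  expect_equal(unname(tortuosity_stats(g2)["tau_mean"]),
               unname(tortuosity_stats(g1)["tau_mean"]), tolerance = 1e-9)
  expect_equal(unname(bifurcation_angle_stats(g2)["ba_mean"]),
               unname(bifurcation_angle_stats(g1)["ba_mean"]),
               tolerance = 1e-6)
})

test_that("2D vessel density on any slice of a z-uniform volume equals 3D", {
  disk <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21)
    disk[i, j] <- (i - 11)^2 + (j - 11)^2 <= 36
  arr <- array(disk, c(21, 21, 8))
  v <- voxel_volume(arr, c(0.1, 0.1, 0.5))
  b3 <- quantify(v, mode = "3D")
  b2 <- quantify(v, mode = "2D")
  expect_equal(b2$vd, b3$vd, tolerance = 1e-12)
})

test_that("2D mode analyzes the largest lesion cross-section only", {
  # vessel on slice 2 only; lesion mask largest on slice 2
  arr <- array(FALSE, c(30, 30, 4))
  arr[15, 5:25, 2] <- TRUE
  m <- array(FALSE, c(30, 30, 4))
  m[10:20, 10:20, 2] <- TRUE
  m[14:16, 14:16, 3] <- TRUE
  v <- voxel_volume(arr, c(1, 1, 1))
  mask <- voxel_volume(m, c(1, 1, 1))
  b <- quantify(v, mask, mode = "2D",
                config = quantify_config(dilate_mm = 10))
  expect_identical(b$mode, "2D")
  expect_identical(b$nv, 1L)
  expect_gt(b$vd, 0)
})
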