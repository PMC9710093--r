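test_that("tube phantoms carry exact analytic truths", {
  tube <- fix_tube()$ph
  expect_equal(tube$truth$true_tortuosity, 1.0)
  expect_equal(tube$truth$true_diameters, 1.0)

  arc <- fix_arc()$ph
  expect_equal(arc$truth$true_tortuosity, pi / 2, tolerance = 1e-12)

  sine <- centerline_spec("sinusoid", length = 12, amplitude = 1, period = 4,
                          spacing = iso01)
  tau <- vesselmorph:::analytic_tortuosity(sine)
  expect_gt(tau, 1.2) # strongly tortuous by construction
})

test_that("rasterized volume fraction matches the spherocylinder analytic value", {
  ph <- make_tube(centerline_spec("straight", length = 15, radius = 1.0,
                                  spacing = iso01))
  measured <- mean(ph$volume$data)
  expect_equal(measured, ph$truth$true_volume_fraction, tolerance = 0.02)
})

test_that("rasterization error decreases with finer spacing", {
  err <- vapply(c(0.2, 0.1), function(h) {
    ph <- make_tube(centerline_spec("straight", length = 12, radius = 1.0,
                                    spacing = rep(h, 3)))
    abs(mean(ph$volume$data) / ph$truth$true_volume_fraction - 1)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("physical-unit truths are identical across grid anisotropy", {
  sp <- centerline_spec("arc", length = 15, radius = 0.5, arc_angle = pi,
                        spacing = c(0.1, 0.1, 0.5))
  sp_iso <- sp
  sp_iso$spacing <- iso01
  t1 <- make_tube(sp)$truth
  t2 <- make_tube(sp_iso)$truth
  expect_equal(t1$true_tortuosity, t2$true_tortuosity)
  expect_equal(t1$true_diameters, t2$true_diameters)
})

test_that("tube rejects a radius below one voxel", {
  expect_error(make_tube(centerline_spec("straight", radius = 0.3,
                                         spacing = c(0.1, 0.1, 0.5))),
               "smaller than one voxel")
})

test_that("tree truths follow the configured branching law", {
  y <- fix_ytree()$ph
  expect_equal(y$truth$true_murray_deviation, 0, tolerance = 1e-12)
  expect_equal(y$truth$true_bifurcation_angles, 90)
  expect_identical(y$truth$true_nb, 1L)
  expect_identical(y$truth$true_nv, 3L)

  eq <- fix_equal_y_fine()$ph
  expect_equal(eq$truth$true_murray_deviation, 1.0, tolerance = 1e-12)

  t2 <- fix_tree_depth2()$ph
  expect_identical(t2$truth$true_nb, 3L)
  expect_identical(t2$truth$true_nv, 7L)
})

test_that("degenerate tree configurations are rejected", {
  expect_error(make_tree(centerline_spec("tree", length = 6, radius = 0.15,
                                         depth = 2, spacing = iso01)),
               "smaller than one voxel")
  expect_error(make_tree(centerline_spec("tree", length = 8, radius = 0.45,
                                         depth = 3, daughter_angle = 30,
                                         length_decay = 1.3,
                                         spacing = iso01)),
               "self-intersecting")
})

test_that("cohorts are reproducible and labels/classes validated", {
  c1 <- make_cohort(2, 2, seed = 9)
  c2 <- make_cohort(2, 2, seed = 9)
  expect_identical(lapply(c1, function(l) l$volume$data),
                   lapply(c2, function(l) l$volume$data))
  expect_identical(vapply(c1, function(l) l$label, ""),
                   c("benign", "benign", "malignant", "malignant"))
  expect_error(make_cohort(0, 5), "at least 2")
})

test_that("configured effects separate the classes on true vessel density", {
  coh <- make_cohort(20, 20, seed = 31)
  vd <- vapply(coh, function(l) l$truth$true_vd, 0)
  lab <- vapply(coh, function(l) l$label, "")
  w <- wilcoxon_rank_sum(vd[lab == "malignant"], vd[lab == "benign"])
  expect_lt(w$p_value, 0.05)
  expect_gt(median(vd[lab == "malignant"]), median(vd[lab == "benign"]))
})

test_that("a zero-variance identical-class configuration warns but runs", {
  eff <- cohort_effects()
  eff$benign[c("n_sdlog", "diameter_sdlog", "length_sdlog")] <- list(0, 0, 0)
  eff$malignant <- eff$benign
  expect_warning(make_cohort(2, 2, effects = eff, seed = 3), "degenerate")
})
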