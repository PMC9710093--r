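test_that("empty and invalid inputs are handled at the boundary", {
  ev <- voxel_volume(array(FALSE, c(6, 6, 3)), c(0.1, 0.1, 0.5))
  sk <- extract_skeleton(ev)
  expect_false(any(sk$data))
  g <- build_graph(sk, distance_transform(ev))
  expect_identical(length(g$segments), 0L)
  expect_identical(nrow(g$nodes), 0L)
  iv <- voxel_volume(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  expect_error(extract_skeleton(iv), "binary")
})

test_that("a straight tube thins to a single simple path with accurate endpoints", {
  fx <- fix_tube()
  g <- fx$graph
  expect_identical(unname(count_stats(g)), c(0L, 1L))
  # one-voxel-wide 26-connected simple path: every voxel has degree <= 2
  tg <- vesselmorph:::trace_voxel_graph(g$skeleton, two_d = FALSE)
  expect_lte(max(tg$deg), 2)
  expect_identical(sum(tg$deg == 1), 2L)
  # endpoints within one voxel of the true centerline ends
  cl <- fx$ph$truth$centerlines[[1]]
  ends_true <- cl[c(1, nrow(cl)), , drop = FALSE]
  ends_meas <- as.matrix(g$nodes[g$nodes$kind == "endpoint",
                                 c("x", "y", "z")])
  d <- vapply(1:2, function(i)
    min(sqrt(rowSums(sweep(ends_meas, 2, ends_true[i, ])^2))), 0)
  expect_lt(max(d), max(fx$ph$volume$spacing) + 1e-9)
})

test_that("a Y tree yields one branch node and a ring yields one cyclic segment", {
  gy <- fix_ytree()$graph
  expect_identical(unname(count_stats(gy)), c(1L, 3L))
  expect_identical(sum(gy$nodes$kind == "endpoint"), 3L)

  ring <- make_tube(centerline_spec("arc", length = 18, radius = 0.4,
                                    arc_angle = 2 * pi, spacing = iso01))
  gr <- vessel_graph(ring$volume, prune = pc_recover)
  expect_identical(unname(count_stats(gr)), c(0L, 1L))
  expect_identical(sum(gr$nodes$kind == "endpoint"), 0L)
  expect_identical(gr$nodes$kind, "loop")
  s <- gr$segments[[1]]
  expect_identical(s$voxels[1], s$voxels[length(s$voxels)]) # closed
})

test_that("radius profiles report distance-transform calibers with known bias", {
  fx <- fix_tube()
  g <- fx$graph
  dt <- distance_transform(fx$ph$volume)
  r <- radius_profile(g$segments[[1]], dt)
  mid <- r[seq(floor(length(r) * 0.25), ceiling(length(r) * 0.75))]
  expect_true(all(abs(2 * mid - 1.0) <= 0.1 + 1e-9)) # +-1 voxel of truth

  # one-voxel-wide line: diameter 2 x EDT ~ 2 voxels (small-vessel bias)
  line <- array(FALSE, c(5, 40, 5)); line[3, 3:38, 3] <- TRUE
  lv <- voxel_volume(line, c(1, 1, 1))
  dtl <- distance_transform(lv)
  gl <- build_graph(extract_skeleton(lv), dtl)
  expect_equal(unname(diameter_stats(gl)["d_mean"]), 2, tolerance = 1e-9)

  bad <- list(voxels = which(!fx$ph$volume$data)[1])
  expect_error(radius_profile(bad, dt), "outside the vessel mask")
})

test_that("tapering trees have nonincreasing caliber from root to leaves", {
  g <- fix_tree_depth2()$graph
  segmean <- vapply(g$segments, function(s) mean(s$radius), 0)
  leaf <- vapply(g$segments, function(s) {
    kinds <- g$nodes$kind[s$nodes]
    any(kinds == "endpoint") && any(kinds == "branch")
  }, TRUE)
  # the root segment also touches an endpoint; it is the widest segment
  root <- which.max(segmean)
  expect_true(all(segmean[leaf & seq_along(segmean) != root] <
                    segmean[root]))
  # generation calibers: root ~0.5, mid ~0.397, leaves ~0.315
  expect_equal(sort(segmean, decreasing = TRUE)[1], 0.5, tolerance = 0.12)
  expect_lt(min(segmean), 0.38)
})

test_that("thinning preserves the connected-component count", {
  two <- rasterize_tubes(
    list(cbind(0, seq(0, 8, 0.05), 0), cbind(4, seq(0, 8, 0.05), 0)),
    radii = c(0.4, 0.4), spacing = iso01)
  vol <- two$volume
  skel <- extract_skeleton(vol)
  comp_n <- function(arr) {
    tg <- vesselmorph:::trace_voxel_graph(arr, two_d = FALSE)
    length(unique(vesselmorph:::component_membership(tg)))
  }
  expect_identical(comp_n(vol$data), 2L)
  expect_identical(comp_n(skel$data), 2L)
  g <- build_graph(skel, distance_transform(vol))
  expect_identical(unname(count_stats(g)), c(0L, 2L))
})

test_that("acyclic skeleton graphs satisfy segments = nodes - 1 per component", {
  for (fx in list(fix_tube(), fix_ytree(), fix_tree_depth2(),
                  fix_tree_depth3())) {
    g <- fx$graph
    expect_identical(length(g$segments), nrow(g$nodes) - 1L)
  }
})

test_that("isotropic 2x upsampling preserves topology and physical lengths", {
  coarse <- fix_ytree()
  fine <- fix_murray_fine() # same tree geometry at half the spacing
  gc <- coarse$graph; gf <- fine$graph
  expect_identical(count_stats(gc), count_stats(gf))
  arc_c <- sum(vapply(gc$segments, function(s) s$arc_length, 0))
  arc_f <- sum(vapply(gf$segments, function(s) s$arc_length, 0))
  expect_lt(abs(arc_c / arc_f - 1), 0.05)
})

test_that("pruning an already-pruned skeleton is a no-op", {
  fx <- fix_tree_depth2()
  g1 <- fx$graph
  dt <- distance_transform(fx$ph$volume)
  sk1 <- voxel_volume(array(g1$skeleton, dim(fx$ph$volume$data)),
                      fx$ph$volume$spacing)
  g2 <- build_graph(sk1, dt, prune = prune_config()) # no further extension
  expect_identical(count_stats(g1), count_stats(g2))
  expect_identical(which(g1$skeleton), which(g2$skeleton))
})
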