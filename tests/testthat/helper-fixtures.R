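# Shared phantom fixtures, built once per test session (rasterization and
# thinning of the finer fixtures take a few seconds each).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# pruning used for phantom-recovery checks: tangent end extension on
pc_recover <- prune_config(extend_ends = TRUE)

iso01 <- c(0.1, 0.1, 0.1)
iso005 <- c(0.05, 0.05, 0.05)

fix_tube <- function() fixture("tube", function() {
  ph <- make_tube(centerline_spec("straight", length = 20, radius = 0.5,
                                  spacing = iso01))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

fix_arc <- function() fixture("arc", function() {
  ph <- make_tube(centerline_spec("arc", length = 15, radius = 0.3,
                                  arc_angle = pi, spacing = iso01))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

fix_ytree <- function() fixture("ytree", function() {
  ph <- make_tree(centerline_spec("tree", length = 8, radius = 0.4,
                                  depth = 1, daughter_angle = 90,
                                  spacing = iso01))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

fix_tree_depth2 <- function() fixture("tree2", function() {
  ph <- make_tree(centerline_spec("tree", length = 8, radius = 0.5,
                                  depth = 2, daughter_angle = 70,
                                  spacing = iso01))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

fix_tree_depth3 <- function() fixture("tree3", function() {
  ph <- make_tree(centerline_spec("tree", length = 9, radius = 0.42,
                                  depth = 3, daughter_angle = 70,
                                  length_decay = 0.55, spacing = iso01))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

# fine-grid fixtures for caliber-sensitive (Murray deviation) checks
fix_murray_fine <- function() fixture("murray_fine", function() {
  ph <- make_tree(centerline_spec("tree", length = 8, radius = 0.4,
                                  depth = 1, daughter_angle = 90,
                                  spacing = iso005))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

fix_equal_y_fine <- function() fixture("equal_y_fine", function() {
  ph <- make_tree(centerline_spec("tree", length = 6, radius = 0.4,
                                  depth = 1, daughter_angle = 90,
                                  daughter_scale = 1, spacing = iso005))
  list(ph = ph, graph = vessel_graph(ph$volume, prune = pc_recover))
})

# independent oracles -------------------------------------------------------

# exhaustive-enumeration two-sided Wilcoxon rank-sum p-value (no ties)
wilcox_enum_oracle <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ws <- apply(utils::combn(N, m), 2, function(idx) sum(r[idx])) -
    m * (m + 1) / 2
  mu <- m * (N - m) / 2
  p <- if (w_obs > mu) 2 * mean(ws >= w_obs) else 2 * mean(ws <= w_obs)
  min(1, p)
}

# brute-force pair-counting AUC (ties count one half)
auc_pair_oracle <- function(scores, labels, positive = "malignant") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# rank-based AUC for fast bootstrap loops
auc_rank <- function(scores, is_pos) {
  m <- sum(is_pos); n <- sum(!is_pos)
  r <- rank(scores)
  (sum(r[is_pos]) - m * (m + 1) / 2) / (m * n)
}
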