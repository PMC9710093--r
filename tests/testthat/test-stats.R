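test_that("Wilcoxon rank-sum matches exhaustive enumeration when exact", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p_value, 1 / 3)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(5) + rep / 4
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcox_enum_oracle(x, y))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("the normal approximation tracks enumeration closely beyond n = 12", {
  set.seed(23)
  x <- rnorm(6); y <- rnorm(7) + 0.5 # combined n = 13: approximation path
  w <- wilcoxon_rank_sum(x, y)
  expect_false(w$exact)
  expect_lt(abs(w$p_value - wilcox_enum_oracle(x, y)), 0.01)
})

test_that("logistic fitting recovers generative coefficients within 10%", {
  set.seed(42)
  n <- 2000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, stats::plogis(-0.5 + 1.0 * X[, 1] - 1.5 * X[, 2]))
  d <- data.frame(X, label = ifelse(y == 1, "malignant", "benign"))
  m <- fit_logistic(d, c("x1", "x2"))
  expect_false(m$separation)
  expect_lt(abs(m$intercept / -0.5 - 1), 0.1)
  expect_lt(abs(m$coefficients["x1"] / 1.0 - 1), 0.1)
  expect_lt(abs(m$coefficients["x2"] / -1.5 - 1), 0.1)
})

test_that("separation and degenerate features are flagged, not fatal", {
  d <- data.frame(x = c(rep(0, 10), rep(1, 10)),
                  label = rep(c("benign", "malignant"), each = 10))
  m <- suppressWarnings(fit_logistic(d, "x"))
  expect_true(m$separation)
  p <- malignancy_probability(m, matrix(d$x, ncol = 1))
  expect_true(all(p[d$label == "malignant"] > 0.99))
  expect_true(all(p[d$label == "benign"] < 0.01))

  d$cst <- 1
  expect_warning(fit_logistic(d, c("x", "cst")), "constant")
  expect_error(fit_logistic(data.frame(x = 1:4, label = rep("benign", 4)),
                            "x"), "both classes")

  set.seed(8)
  d2 <- data.frame(x = rnorm(400),
                   label = sample(c("benign", "malignant"), 400, TRUE))
  m2 <- fit_logistic(d2, "x")
  expect_lt(abs(m2$coefficients["x"]), 0.25) # independent feature: near zero
})

test_that("the malignancy-probability equation is the inverse logit", {
  m0 <- fit_logistic(data.frame(x = c(0, 1, 0, 1, 0.5),
                                label = c("benign", "malignant", "benign",
                                          "malignant", "benign")), "x")
  m0$intercept <- 0; m0$coefficients[] <- 0
  expect_identical(unname(malignancy_probability(m0, c(x = 3))), 0.5)

  m0$intercept <- 1; m0$coefficients[] <- 2
  expect_equal(unname(malignancy_probability(m0, c(x = 0.5))),
               1 / (1 + exp(-2)), tolerance = 1e-12)

  big <- vapply(c(1, 5, 20, 100), function(s)
    unname(malignancy_probability(m0, c(x = s))), 0)
  expect_true(all(diff(big) >= 0) && big[4] > 1 - 1e-10)
  expect_error(malignancy_probability(m0, c(1, 2)), "length")
})

test_that("LOOCV probabilities are pooled, exchangeable and honest", {
  set.seed(19)
  n <- 40
  d <- data.frame(x = c(rnorm(n / 2), rnorm(n / 2, 6)),
                  z = rnorm(n),
                  label = rep(c("benign", "malignant"), each = n / 2))
  p <- loocv_predict(d, c("x", "z"))
  expect_length(p, n)
  expect_equal(roc_auc(p, d$label)$auc, 1.0) # separable margin >> noise

  perm <- sample(n)
  p2 <- loocv_predict(d[perm, ], c("x", "z"))
  expect_equal(p2, p[perm], tolerance = 1e-9)

  expect_error(loocv_predict(d[1:2, ], c("x", "z")), "at least 3")
})

test_that("AUC equals the pair-counting oracle and the trapezoidal area", {
  set.seed(3)
  for (rep in 1:5) {
    sc <- round(rnorm(30), 1) # ties likely
    lb <- sample(c("benign", "malignant"), 30, TRUE, prob = c(0.6, 0.4))
    if (length(unique(lb)) < 2) next
    r <- roc_auc(sc, lb)
    expect_equal(r$auc, auc_pair_oracle(sc, lb))
    trap <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) +
                                     utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_true(r$ci[1] <= r$auc && r$ci[2] >= r$auc)
  }
})

test_that("AUC conventions: perfect ranking, all ties, monotone invariance", {
  lb <- rep(c("benign", "malignant"), each = 5)
  expect_identical(roc_auc(c(1:5 / 10, 6:10 / 10), lb)$auc, 1)
  expect_identical(roc_auc(rep(0.5, 10), lb)$auc, 0.5)
  set.seed(5)
  sc <- rnorm(30); lb2 <- sample(c("benign", "malignant"), 30, TRUE)
  if (length(unique(lb2)) == 2)
    expect_equal(roc_auc(sc, lb2)$auc, roc_auc(stats::plogis(3 * sc), lb2)$auc)
  expect_error(roc_auc(1:4, rep("benign", 4)), "both classes")
})

test_that("the ROC layer agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- c(rnorm(30), rnorm(25, 1))
  lb <- rep(c("benign", "malignant"), c(30, 25))
  r <- roc_auc(sc, lb)
  pr <- pROC::roc(lb, sc, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pr$auc), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci, ci[c(1, 3)], tolerance = 1e-9)

  sc2 <- sc + rnorm(55, 0, 0.8)
  dl <- delong_paired_test(sc, sc2, lb)
  pt <- pROC::roc.test(pr, pROC::roc(lb, sc2, levels = c("benign",
                                                         "malignant"),
                                     direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p_value, pt$p.value, tolerance = 1e-9)
})

test_that("DeLong identities and degenerate conventions hold", {
  set.seed(13)
  sc <- rnorm(40)
  lb <- rep(c("benign", "malignant"), 20)
  dl <- delong_paired_test(sc, sc, lb)
  expect_identical(dl$p_value, 1)
  expect_true(dl$degenerate)
  expect_identical(dl$delta, 0)
  # placement AUC equals pair counting on random fixtures
  for (rep in 1:5) {
    s <- round(rnorm(25), 1)
    l <- sample(c("benign", "malignant"), 25, TRUE)
    if (length(unique(l)) < 2) next
    pl <- vesselmorph:::auc_placements(s, l, "malignant")
    expect_equal(pl$auc, auc_pair_oracle(s, l))
  }
})

test_that("confusion metrics reproduce the reported screening arithmetic", {
  m <- confusion_metrics(33, 1, 56, 3)
  expect_identical(unname(format_metrics(m)),
                   c(91.7, 98.2, 97.1, 94.9, 0.085))

  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_identical(unname(format_metrics(perfect)), c(100, 100, 100, 100, 0))

  # single-plane counts reconstructed from reported rates (36/57 cohort)
  tp <- round(0.861 * 36); fn <- 36 - tp
  tn <- round(0.754 * 57); fp <- 57 - tn
  m2 <- confusion_metrics(tp, fp, tn, fn)
  f2 <- format_metrics(m2)
  expect_identical(unname(f2[c("nlr", "ppv_pct", "npv_pct")]),
                   c(0.184, 68.9, 89.6))

  expect_error(confusion_metrics(-1, 0, 5, 5), "nonnegative")
  expect_error(confusion_metrics(0, 0, 5, 0), "nonempty")
  expect_true(is.na(confusion_metrics(0, 0, 5, 3)$ppv))
})

test_that("cohort analysis assembles the statistical report", {
  set.seed(29)
  n <- 30
  tab <- data.frame(
    vd = c(rlnorm(n, -3, 0.3), rlnorm(n, -2, 0.3)),
    mvfd = c(rnorm(n, 0.9, 0.15), rnorm(n, 1.2, 0.15)),
    tau_max = c(rlnorm(n, 0.3, 0.3), rlnorm(n, 1, 0.4)),
    nv = c(rpois(n, 4), rpois(n, 12)),
    nb = c(rpois(n, 1), rpois(n, 6)),
    d_mean = rnorm(2 * n, 0.65, 0.1),
    md_mean = c(rep(NA, 5), runif(2 * n - 5)),
    label = rep(c("benign", "malignant"), each = n))
  a <- analyze_cohort(tab)
  expect_s3_class(a$roc, "roc_result")
  expect_length(a$loocv_probabilities, 2 * n)
  expect_gt(a$roc$auc, 0.8)
  expect_true(all(c("vd", "nb", "md_mean") %in% a$wilcoxon$biomarker))
  expect_lt(a$wilcoxon$p_value[a$wilcoxon$biomarker == "vd"], 0.05)
  expect_equal(a$wilcoxon$n_defined[a$wilcoxon$biomarker == "md_mean"],
               2 * n - 5)
  expect_equal(sum(a$roc$confusion), 2 * n)
})
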