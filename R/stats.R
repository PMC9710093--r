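#' Wilcoxon rank-sum comparison of a biomarker by group
#'
#' Two-sample Wilcoxon rank-sum test with a fixed exactness contract: the
#' exact null distribution is enumerated when the combined sample size is
#' at most 12 and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. Two-sided by default, with
#' the conventional 0.05 significance level.
#'
#' @param x,y numeric samples (both nonempty; `NA` removed).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `p_value`, `statistic` (the Mann-Whitney U of `x`),
#'   and `exact` (whether the exact distribution was used).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       exact = exact)
}

#' Fit the multi-variable logistic malignancy model
#'
#' Maximum-likelihood logistic regression of malignancy status on a set of
#' biomarkers, fitted by iteratively reweighted least squares on z-scored
#' features (coefficients are reported on the original scale). When
#' separation is detected (diverging coefficients / fitted probabilities
#' pinned at 0 or 1) the model is refitted with a small ridge penalty
#' (lambda = 1e-4 on the standardized features) and flagged. Constant
#' features are dropped with a warning.
#'
#' @param cohort data frame with the feature columns and a label column.
#' @param features character vector of feature column names; the default
#'   six-biomarker panel is `vd`, `mvfd`, `tau_max`, `nv`, `nb`, `d_mean`.
#' @param label_col name of the label column.
#' @param positive label value treated as the event (malignant).
#' @return object of class `malignancy_model`: list with `intercept`,
#'   `coefficients` (named, original scale), `features`, `separation`
#'   flag, and the standardization used.
#' @export
fit_logistic <- function(cohort,
                         features = c("vd", "mvfd", "tau_max", "nv", "nb",
                                      "d_mean"),
                         label_col = "label", positive = "malignant") {
  stopifnot(all(features %in% names(cohort)), label_col %in% names(cohort))
  y <- as.integer(cohort[[label_col]] == positive)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(cohort[features])
  if (any(!is.finite(X))) stop("missing feature values in the model matrix")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(features[!keep], collapse = ", "))
    features <- features[keep]
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2, mus), 2, sds, "/")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, Z), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta)) || max(abs(beta[-1])) > 15)
    sep <- TRUE
  if (sep)
    beta <- ridge_logistic(cbind(1, Z), y, lambda = 1e-4)
  coefs <- beta[-1] / sds
  intercept <- beta[1] - sum(beta[-1] * mus / sds)
  structure(list(intercept = unname(intercept),
                 coefficients = stats::setNames(coefs, features),
                 features = features, separation = sep,
                 center = mus, scale = sds,
                 n = length(features)),
            class = "malignancy_model")
}

# IRLS with an L2 penalty on the non-intercept coefficients
ridge_logistic <- function(Xd, y, lambda = 1e-4, maxit = 100L,
                           tol = 1e-10) {
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    bn <- solve(H, crossprod(Xd, w * z))
    if (max(abs(bn - beta)) < tol) { beta <- drop(bn); break }
    beta <- drop(bn)
  }
  beta
}

#' @export
print.malignancy_model <- function(x, ...) {
  cat("<malignancy_model> logit^-1(B + sum C_i P_i)\n")
  cat(sprintf("  B = %.4g%s\n", x$intercept,
              if (x$separation) "  [separation: ridge-stabilized]" else ""))
  for (f in x$features)
    cat(sprintf("  C[%s] = %.4g\n", f, x$coefficients[f]))
  invisible(x)
}

#' Malignancy probability of a lesion
#'
#' Evaluates `logit^-1(B + sum_i C_i P_i)` with
#' `logit^-1(a) = 1 / (1 + exp(-a))` for one feature vector or a feature
#' matrix (rows = lesions).
#'
#' @param model a `malignancy_model` from [fit_logistic()].
#' @param P named numeric vector, matrix or data frame of biomarker values
#'   matching the model features.
#' @return probability (or vector of probabilities) in `(0, 1)`.
#' @export
malignancy_probability <- function(model, P) {
  stopifnot(inherits(model, "malignancy_model"))
  if (is.data.frame(P)) P <- as.matrix(P[model$features])
  if (is.null(dim(P))) {
    if (length(P) != length(model$features))
      stop("feature vector length does not match the model")
    P <- matrix(P, nrow = 1)
  } else if (ncol(P) != length(model$features))
    stop("feature matrix does not match the model features")
  eta <- model$intercept + drop(P %*% model$coefficients)
  stats::plogis(eta)
}

#' Pooled leave-one-out cross-validated probabilities
#'
#' For each lesion, fits the logistic model on the remaining `n - 1`
#' lesions and predicts the held-out lesion; the `n` held-out
#' probabilities are pooled (in input order) for honest ROC evaluation.
#' Deterministic; a fold whose training set degenerates to one class is
#' refused by the fitter, so `n >= 3` with both classes at least twice is
#' required in practice.
#'
#' @inheritParams fit_logistic
#' @return numeric vector of pooled held-out probabilities, one per row.
#' @export
loocv_predict <- function(cohort,
                          features = c("vd", "mvfd", "tau_max", "nv", "nb",
                                       "d_mean"),
                          label_col = "label", positive = "malignant") {
  n <- nrow(cohort)
  if (n < 3) stop("LOOCV needs at least 3 lesions")
  probs <- numeric(n)
  for (i in seq_len(n)) {
    m <- suppressWarnings(
      fit_logistic(cohort[-i, , drop = FALSE], features, label_col,
                   positive))
    probs[i] <- malignancy_probability(
      m, as.matrix(cohort[i, m$features, drop = FALSE]))
  }
  probs
}

# Mann-Whitney pair-counting AUC (ties count 1/2) and DeLong placements
auc_placements <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  v10 <- vapply(pos, function(p)
    (sum(p > neg) + 0.5 * sum(p == neg)) / n, 0)
  v01 <- vapply(neg, function(q)
    (sum(pos > q) + 0.5 * sum(pos == q)) / m, 0)
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve, AUC with DeLong confidence interval, and optimal cut-point
#'
#' Builds the empirical ROC curve of malignancy probabilities, computes
#' the AUC by the Mann-Whitney pair-counting identity (tied pairs count
#' one half), a 95% Wald confidence interval from the DeLong variance
#' (clipped to `[0, 1]`), the optimal cut-point as the ROC point closest
#' to (0, 1) (ties resolved toward higher specificity), and the confusion
#' metrics at that cut-point.
#'
#' @param probabilities numeric scores (higher = more malignant).
#' @param labels vector of class labels.
#' @param positive label treated as malignant.
#' @param conf_level confidence level for the AUC interval.
#' @return object of class `roc_result`: list with `roc` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `ci`, `cutpoint`, `confusion`
#'   (TP/FP/TN/FN) and `metrics` (see [confusion_metrics()]).
#' @export
roc_auc <- function(probabilities, labels, positive = "malignant",
                    conf_level = 0.95) {
  stopifnot(length(probabilities) == length(labels))
  pl <- auc_placements(probabilities, labels, positive)
  # ROC: predict positive when score >= threshold; thresholds at the
  # observed scores (descending), plus one above the maximum
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  pos <- labels == positive
  tpr <- vapply(thr, function(t) sum(probabilities >= t & pos) / pl$m, 0)
  fpr <- vapply(thr, function(t) sum(probabilities >= t & !pos) / pl$n, 0)
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * zq * sqrt(v)))
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  best <- order(d, roc$fpr)[1] # ties toward higher specificity (lower FPR)
  cut <- roc$threshold[best]
  tp <- sum(probabilities >= cut & pos)
  fp <- sum(probabilities >= cut & !pos)
  fn <- pl$m - tp
  tn <- pl$n - fp
  structure(list(probabilities = probabilities, labels = labels,
                 positive = positive, roc = roc, auc = pl$auc,
                 ci = ci, auc_var = v, cutpoint = cut,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = confusion_metrics(tp, fp, tn, fn)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.0f%% CI %.3f-%.3f), cut-point %.3g\n",
              x$auc, 95, x$ci[1], x$ci[2], x$cutpoint))
  m <- x$metrics
  cat(sprintf("  sens %.1f%% spec %.1f%% PPV %.1f%% NPV %.1f%% NLR %.3f\n",
              100 * m$sensitivity, 100 * m$specificity, 100 * m$ppv,
              100 * m$npv, m$nlr))
  invisible(x)
}

#' DeLong's test for two paired ROC curves
#'
#' Compares the AUCs of two probability vectors evaluated on the same
#' lesions with the same labels, using the DeLong covariance of the paired
#' placement values and a two-sided z-test on the AUC difference. When the
#' two rankings are identical (zero variance of the difference) the
#' p-value is 1 by convention and the result is flagged.
#'
#' @param probs_a,probs_b paired probability vectors.
#' @param labels class labels (same lesions for both).
#' @param positive label treated as malignant.
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p_value`,
#'   `degenerate`.
#' @export
delong_paired_test <- function(probs_a, probs_b, labels,
                               positive = "malignant") {
  stopifnot(length(probs_a) == length(labels),
            length(probs_b) == length(labels))
  pa <- auc_placements(probs_a, labels, positive)
  pb <- auc_placements(probs_b, labels, positive)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = 0,
                p_value = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values, and the negative likelihood ratio
#' `(1 - sensitivity) / specificity`. For reporting, percentages are
#' conventionally rounded to one decimal and the NLR to three
#' ([format_metrics()]).
#'
#' @param tp,fp,tn,fn nonnegative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0` are required.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`, `nlr`
#'   (fractions; `ppv` is `NA` when no positive calls were made).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("each true class must be nonempty")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       nlr = (1 - sens) / spec)
}

#' @rdname confusion_metrics
#' @param metrics a list from `confusion_metrics`.
#' @export
format_metrics <- function(metrics) {
  c(sensitivity_pct = round(100 * metrics$sensitivity, 1),
    specificity_pct = round(100 * metrics$specificity, 1),
    ppv_pct = round(100 * metrics$ppv, 1),
    npv_pct = round(100 * metrics$npv, 1),
    nlr = round(metrics$nlr, 3))
}

#' Full cohort analysis: group comparisons and the pooled LOOCV model
#'
#' Runs the statistical layer on a feature table: Wilcoxon rank-sum
#' comparison of every biomarker by malignancy status (branch-dependent
#' parameters compared on the lesions where they are defined; no
#' multiplicity correction, by design), the full-data logistic fit whose
#' coefficients populate the malignancy-probability equation, pooled
#' leave-one-out cross-validated probabilities, and the ROC evaluation of
#' those pooled predictions.
#'
#' @param cohort data frame of biomarkers with a label column.
#' @param features model features (defaults to the six-biomarker panel).
#' @param label_col,positive label column and positive class.
#' @param missing how to handle missing model-feature values:
#'   `"error"` (they should not occur for the default panel) or
#'   `"impute-neutral"`, which substitutes the no-vessel neutral values
#'   (0 for densities/counts, 1 for tortuosity).
#' @return list of class `cohort_analysis` with `wilcoxon` (data frame),
#'   `model`, `loocv_probabilities`, and `roc` (a `roc_result`).
#' @export
analyze_cohort <- function(cohort,
                           features = c("vd", "mvfd", "tau_max", "nv", "nb",
                                        "d_mean"),
                           label_col = "label", positive = "malignant",
                           missing = c("error", "impute-neutral")) {
  missing <- match.arg(missing)
  biomarkers <- intersect(
    c("vd", "d_mean", "d_max", "tau_mean", "tau_max", "md_mean", "md_max",
      "ba_mean", "ba_max", "mvfd", "nb", "nv"), names(cohort))
  grp <- cohort[[label_col]] == positive
  wil <- do.call(rbind, lapply(biomarkers, function(b) {
    x <- cohort[[b]][grp]; y <- cohort[[b]][!grp]
    n_def <- sum(!is.na(x)) + sum(!is.na(y))
    p <- if (sum(!is.na(x)) && sum(!is.na(y)))
      wilcoxon_rank_sum(x, y)$p_value else NA_real_
    data.frame(biomarker = b, n_defined = n_def, p_value = p,
               significant = !is.na(p) & p < 0.05)
  }))
  mdl_tab <- cohort
  if (missing == "impute-neutral") {
    neutral <- c(vd = 0, mvfd = 0, nv = 0, nb = 0, d_mean = 0, d_max = 0,
                 tau_mean = 1, tau_max = 1)
    for (f in features) {
      bad <- !is.finite(mdl_tab[[f]])
      if (any(bad))
        mdl_tab[[f]][bad] <- if (f %in% names(neutral)) neutral[[f]] else 0
    }
  }
  model <- suppressWarnings(
    fit_logistic(mdl_tab, features, label_col, positive))
  probs <- loocv_predict(mdl_tab, features, label_col, positive)
  roc <- roc_auc(probs, mdl_tab[[label_col]], positive)
  structure(list(wilcoxon = wil, model = model,
                 loocv_probabilities = probs, roc = roc,
                 features = features),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  print(x$model)
  print(x$roc)
  sig <- x$wilcoxon$biomarker[x$wilcoxon$significant]
  cat("  Wilcoxon p < 0.05:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
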