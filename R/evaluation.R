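#' Binary confusion counts (one-vs-rest)
#'
#' Counts true/false positives and negatives with `positive` as the
#' positive class and everything else negative. Rejected predictions must
#' be filtered out beforehand; they carry no confusion information.
#'
#' @param truth,predicted equal-length label vectors.
#' @param positive the positive class label.
#' @return A list of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    abort_lcms("truth and predicted must have equal length", "lcmsnet_parameter_error")
  }
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(list(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
                 FP = sum(!tpos & ppos), FN = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`. A zero denominator
#' yields `NA` (explicitly undefined, never silently 0).
#'
#' @param counts a [confusion_counts()] (or list with TP, TN, FP, FN).
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `f1`.
#' @examples
#' binary_metrics(confusion_counts(c("A","A","B","B"), c("A","B","B","B"), "A"))
#' @export
binary_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) {
    abort_lcms("confusion counts must be non-negative", "lcmsnet_parameter_error")
  }
  total <- TP + TN + FP + FN
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = rat(TP + TN, total),
    sensitivity = rat(TP, TP + FN),
    specificity = rat(TN, TN + FP),
    f1 = rat(2 * TP, 2 * TP + FP + FN)
  ), class = "metrics_report")
}

#' Macro one-vs-rest metrics
#'
#' Computes [binary_metrics()] per class (one-vs-rest) and their
#' unweighted (macro) means, excluding per-class values that are undefined
#' (zero denominator) and counting the exclusions. The overall multiclass
#' accuracy -- the fraction of exact label matches -- is reported
#' separately; with imbalanced classes the one-vs-rest per-class
#' accuracies typically exceed it, because they are dominated by the large
#' negative rest group.
#'
#' @param truth,predicted equal-length label vectors (rejected entries
#'   filtered out beforehand).
#' @param classes classes to evaluate; defaults to the sorted union of the
#'   observed labels.
#' @return A list with `per_class` (data.frame of one-vs-rest metrics),
#'   `macro` (macro means), `overall_accuracy` and `n_undefined`.
#' @export
macro_metrics <- function(truth, predicted, classes = NULL) {
  if (!length(truth)) abort_lcms("empty input", "lcmsnet_parameter_error")
  if (length(truth) != length(predicted)) {
    abort_lcms("truth and predicted must have equal length", "lcmsnet_parameter_error")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (length(classes) < 2) abort_lcms("need >= 2 classes", "lcmsnet_parameter_error")
  per <- lapply(classes, function(cl) {
    unlist(binary_metrics(confusion_counts(truth, predicted, cl)))
  })
  per_class <- cbind(data.frame(class = classes, stringsAsFactors = FALSE),
                     do.call(rbind, per))
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1")
  macro <- lapply(metric_names, function(mn) mean(per_class[[mn]], na.rm = TRUE))
  names(macro) <- metric_names
  n_undef <- sum(is.na(per_class[metric_names]))
  if (n_undef > 0) {
    warning(sprintf("%d undefined per-class metric value(s) excluded from macro means",
                    n_undef))
  }
  list(per_class = per_class, macro = macro,
       overall_accuracy = mean(truth == predicted), n_undefined = n_undef)
}

#' Stratified train/test split
#'
#' Assigns each sample to `"train"` or `"test"` so that per-class
#' proportions match the requested test fraction within one sample,
#' deterministically under `seed`.
#'
#' @param labels class labels.
#' @param test_fraction fraction assigned to the test set (default 0.25,
#'   i.e. a 75/25 split).
#' @param seed integer seed.
#' @return Character vector of `"train"` / `"test"` parallel to `labels`.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = 1) {
  check_number(test_fraction, "test_fraction", lower = 0, upper = 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 601))
  out <- rep("train", length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(test_fraction * length(idx))
    if (n_test > 0) out[sample(idx, n_test)] <- "test"
  }
  out
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' over the folds, giving disjoint, exhaustive folds whose class
#' proportions match the global ones within one sample.
#'
#' @param labels class labels; every class must have at least `k` members.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold assignment in `1..k`, parallel to `labels`.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  check_number(k, "k", lower = 2)
  tab <- table(labels)
  if (any(tab < k)) {
    abort_lcms(sprintf("class '%s' has fewer than k=%d members",
                       names(tab)[which.min(tab)], k),
               "lcmsnet_parameter_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 602))
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Wilcoxon signed-rank test for paired classifier scores
#'
#' Ranks the absolute performance differences `d` of two classifiers over
#' N datasets (mid-ranks for ties, zero differences dropped), sums the
#' ranks of positive (`R_plus`) and negative (`R_minus`) differences and
#' forms `T = min(R_plus, R_minus)`. The p-value is exact -- full
#' enumeration of all `2^N'` sign assignments -- for `N' <= 15`, and a
#' normal approximation with tie correction and continuity correction
#' otherwise; `method` can force either.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"greater"` (median difference > 0, default),
#'   `"less"`, or `"two.sided"`.
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @return A list of class `wilcoxon_result`: `differences`, `R_plus`,
#'   `R_minus`, `T`, `p_value`, `method`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("greater", "less", "two.sided"),
                                 method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(d)) abort_lcms("need at least one difference", "lcmsnet_parameter_error")
  d_used <- d[d != 0]
  n <- length(d_used)
  if (n == 0) {
    abort_lcms("all differences are zero; test undefined", "lcmsnet_undefined_test_error")
  }
  r <- rank(abs(d_used))                 # mid-ranks for ties
  R_plus <- sum(r[d_used > 0])
  R_minus <- sum(r[d_used < 0])
  if (method == "auto") method <- if (n <= 15) "exact" else "normal"

  p_from_W <- function(W_all, W_obs) {
    switch(alternative,
      greater = mean(W_all >= W_obs - 1e-9),
      less = mean(W_all <= W_obs + 1e-9),
      two.sided = min(1, 2 * min(mean(W_all >= W_obs - 1e-9),
                                 mean(W_all <= W_obs + 1e-9)))
    )
  }
  if (method == "exact") {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% r)      # R_plus under every sign pattern
    p <- p_from_W(W_all, R_plus)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    z_hi <- (R_plus - mu - 0.5) / sigma  # P(W >= obs), continuity-corrected
    z_lo <- (R_plus - mu + 0.5) / sigma
    p <- switch(alternative,
      greater = stats::pnorm(z_hi, lower.tail = FALSE),
      less = stats::pnorm(z_lo),
      two.sided = min(1, 2 * min(stats::pnorm(z_hi, lower.tail = FALSE),
                                 stats::pnorm(z_lo)))
    )
  }
  structure(list(differences = d, R_plus = R_plus, R_minus = R_minus,
                 T = min(R_plus, R_minus), p_value = p, method = method,
                 n_used = n),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: N'=%d, R+=%g, R-=%g, T=%g, p=%.4g (%s)\n",
              x$n_used, x$R_plus, x$R_minus, x$T, x$p_value, x$method))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values,
#' returned in the original order and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_lcms("p-values must lie in [0, 1]", "lcmsnet_parameter_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare two classifiers over cross-validation folds
#'
#' Convenience wrapper: takes per-fold scores of two models, tests whether
#' model A outperforms model B with [wilcoxon_signed_rank()] on the paired
#' differences, one metric at a time, and adjusts the p-values with
#' [bh_adjust()].
#'
#' @param scores_a,scores_b data.frames of per-fold scores with identical
#'   metric columns (one row per fold).
#' @param alternative passed to [wilcoxon_signed_rank()].
#' @return data.frame with one row per metric: `R_plus`, `R_minus`, `T`,
#'   `p_value`, `p_adjusted`, `method`.
#' @export
compare_models <- function(scores_a, scores_b,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  metrics <- intersect(names(scores_a), names(scores_b))
  metrics <- metrics[vapply(scores_a[metrics], is.numeric, logical(1))]
  if (!length(metrics)) abort_lcms("no shared numeric metric columns", "lcmsnet_parameter_error")
  rows <- lapply(metrics, function(mn) {
    w <- wilcoxon_signed_rank(scores_a[[mn]] - scores_b[[mn]],
                              alternative = alternative)
    data.frame(metric = mn, R_plus = w$R_plus, R_minus = w$R_minus, T = w$T,
               p_value = w$p_value, method = w$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
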