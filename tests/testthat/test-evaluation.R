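test_that("confusion counts enumerate one-vs-rest outcomes", {
  cc <- confusion_counts(c("A", "A", "B", "B"), c("A", "B", "B", "B"), "A")
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 2L, FP = 0L))
  ident <- confusion_counts(c("A", "B"), c("A", "B"), "A")
  expect_equal(ident$FP + ident$FN, 0L)
  absent <- confusion_counts(c("B", "B"), c("B", "A"), "Z")
  expect_equal(absent$TP + absent$FN, 0L)
  expect_error(confusion_counts("A", c("A", "B"), "A"),
               class = "lcmsnet_parameter_error")
})

test_that("binary metrics match the defining ratios", {
  m <- binary_metrics(list(TP = 8, TN = 5, FP = 2, FN = 1))
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$specificity, 5 / 7)
  expect_equal(m$f1, 16 / 19)
  perfect <- binary_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  degen <- binary_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$f1, 0)
  expect_equal(degen$specificity, 1)
  # zero denominators are explicitly undefined
  nd <- binary_metrics(list(TP = 0, FP = 0, FN = 0, TN = 4))
  expect_true(is.na(nd$sensitivity))
  expect_true(is.na(nd$f1))
})

test_that("macro metrics are symmetric and relabeling-invariant", {
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "A")          # symmetric confusion
  mm <- macro_metrics(truth, pred)
  expect_equal(mm$macro$f1, mm$per_class$f1[1])
  # permuting class identities leaves macro values unchanged
  swap <- c(A = "B", B = "A")
  mm2 <- macro_metrics(unname(swap[truth]), unname(swap[pred]))
  expect_equal(mm$macro, mm2$macro)
  expect_equal(mm$overall_accuracy, 0.5)
})

test_that("one-vs-rest accuracies exceed overall accuracy under imbalance", {
  set.seed(3)
  truth <- c(rep("big", 80), rep("mid", 15), rep("rare", 5))
  pred <- truth
  flip <- sample(100, 30)                 # 30% errors
  pred[flip] <- sample(c("big", "mid", "rare"), 30, replace = TRUE)
  mm <- macro_metrics(truth, pred)
  expect_true(all(mm$per_class$accuracy >= mm$overall_accuracy))
})

test_that("stratified splitting preserves class proportions", {
  labels <- c(rep("A", 80), rep("B", 20))
  sp <- stratified_split(labels, test_fraction = 0.25, seed = 5)
  expect_equal(sum(sp == "test" & labels == "A"), 20)
  expect_equal(sum(sp == "test" & labels == "B"), 5)
  expect_identical(sp, stratified_split(labels, 0.25, seed = 5))
  expect_false(identical(sp, stratified_split(labels, 0.25, seed = 6)))
})

test_that("stratified k-fold partitions evenly", {
  labels <- rep(LETTERS[1:5], each = 20)
  fold <- stratified_kfold(labels, k = 10, seed = 2)
  expect_setequal(unique(fold), 1:10)
  for (f in 1:10) {
    expect_equal(unname(table(labels[fold == f])), rep(2L, 5),
                 ignore_attr = TRUE)
  }
  expect_error(stratified_kfold(c("A", rep("B", 20)), k = 5),
               class = "lcmsnet_parameter_error")
})

test_that("wilcoxon ranks and statistic follow the hand computation", {
  w <- wilcoxon_signed_rank(c(1, -2, 3, -4, 5))
  expect_equal(w$R_plus, 9)
  expect_equal(w$R_minus, 6)
  expect_equal(w$T, 6)
  expect_equal(w$R_plus + w$R_minus, 5 * 6 / 2)
  # all-positive differences drive T to 0
  expect_equal(wilcoxon_signed_rank(c(2, 1, 4))$T, 0)
  expect_error(wilcoxon_signed_rank(c(0, 0)),
               class = "lcmsnet_undefined_test_error")
})

test_that("exact p-values equal full sign enumeration and the stats oracle", {
  set.seed(17)
  for (n in c(4, 6, 8)) {
    for (rep in 1:3) {
      d <- round(runif(n, 0.5, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
      d <- d[!duplicated(abs(d))]
      for (alt in c("greater", "less", "two.sided")) {
        w <- wilcoxon_signed_rank(d, alternative = alt)
        expect_equal(w$method, "exact")
        expect_equal(w$p_value, enumerate_wilcoxon_p(d, alt))
        ref <- stats::wilcox.test(d, alternative = alt, exact = TRUE)
        expect_equal(w$p_value, unname(ref$p.value))
      }
    }
  }
  # invariant R+ + R- = N'(N'+1)/2 under ties and zeros
  d <- c(1, -1, 2, 2, -3, 0, 0.5)
  w <- wilcoxon_signed_rank(d)
  expect_equal(w$n_used, 6)
  expect_equal(w$R_plus + w$R_minus, 6 * 7 / 2)
})

test_that("normal approximation tracks the stats oracle for larger N", {
  set.seed(23)
  d <- rnorm(30, 0.3)
  d <- d[d != 0]
  w <- wilcoxon_signed_rank(d, alternative = "greater", method = "normal")
  ref <- stats::wilcox.test(d, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("benjamini-hochberg adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(31)
  for (rep in 1:5) {
    p <- runif(sample(3:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    # monotone when re-sorted by the raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "lcmsnet_parameter_error")
})

test_that("model comparison pairs fold scores and adjusts p-values", {
  set.seed(41)
  a <- data.frame(accuracy = runif(10, 0.7, 0.9), f1 = runif(10, 0.6, 0.8))
  b <- data.frame(accuracy = a$accuracy - 0.05, f1 = a$f1 - 0.02)
  cmp <- compare_models(a, b, alternative = "greater")
  expect_equal(cmp$metric, c("accuracy", "f1"))
  expect_true(all(cmp$p_value < 0.01))   # consistent positive differences
  expect_equal(cmp$p_adjusted, bh_adjust(cmp$p_value))
})
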