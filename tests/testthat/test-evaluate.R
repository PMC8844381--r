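test_that("confusion metrics reproduce printed proportions", {
  # 497 correct calls out of 583 frames -> 85.2% accuracy
  truth <- rep(c(1, 0), c(300, 283))
  pred <- truth
  wrong <- c(1:43, 301:343)  # 86 errors split across classes
  pred[wrong] <- 1 - pred[wrong]
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$n, 583)
  expect_equal(cm$tp + cm$tn, 497)
  expect_equal(round(100 * cm$accuracy, 1), 85.2)
  expect_equal(cm$accuracy,
               (cm$sensitivity * 300 + cm$specificity * 283) / 583)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))

  allpos <- confusion_metrics(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)

  expect_warning(confusion_metrics(c(0, 1), c(0, 0)), "undefined")
  expect_error(confusion_metrics(c(0, 1), c(0)), "length")
})

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(50)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(scores, truth)$auc, brute_auc(scores, truth))
  }
  # curve endpoints span (0,0) to (1,1)
  rr <- roc_auc(runif(20), rep(c(0, 1), 10))
  expect_equal(unlist(rr$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rr$curve[nrow(rr$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  truth <- rbinom(80, 1, 0.5)
  scores <- runif(80) + truth * 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
})

test_that("percentile bootstrap interval behaves as designed", {
  cfg <- eval_config(n_bootstrap = 500, seed = 7)
  expect_equal(unname(bootstrap_ci(rep(3, 20), cfg = cfg)), c(3, 3))
  expect_error(bootstrap_ci(numeric()), "nonempty")
  # deterministic given the seed
  x <- rnorm(50)
  expect_identical(bootstrap_ci(x, cfg = cfg), bootstrap_ci(x, cfg = cfg))
  # interval widens with the level
  ci90 <- bootstrap_ci(x, cfg = eval_config(500, 90, 7))
  ci99 <- bootstrap_ci(x, cfg = eval_config(500, 99, 7))
  expect_lte(ci99[1], ci90[1])
  expect_gte(ci99[2], ci90[2])
  # for large B the binomial-mean interval approaches the normal one
  y <- rep(c(1, 0), c(497, 86))
  ci <- bootstrap_ci(y, cfg = eval_config(10000, 95, 11))
  p <- mean(y); se <- sqrt(p * (1 - p) / length(y))
  expect_equal(unname(ci), p + c(-1.96, 1.96) * se, tolerance = 0.01)
})

test_that("two-proportion z-test matches the pooled-variance closed form", {
  res <- two_proportion_ztest(80, 100, 60, 100)
  expect_equal(res$z, 3.0861, tolerance = 1e-3)
  expect_equal(res$p_value, 0.00203, tolerance = 1e-3)
  eq <- two_proportion_ztest(30, 60, 30, 60)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  swap <- two_proportion_ztest(60, 100, 80, 100)
  expect_equal(swap$z, -res$z)
  expect_equal(swap$p_value, res$p_value)
  expect_true(two_proportion_ztest(0, 10, 0, 10)$degenerate)
  expect_error(two_proportion_ztest(11, 10, 5, 10), "x <= n")
})

test_that("exact Wilcoxon p equals sign-flip enumeration and wilcox.test", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(res$w, 0)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$method, "exact")
  # antisymmetric differences: p = 1
  expect_equal(wilcoxon_signed_rank(c(2, -2, 5, -5))$p_value, 1)
  # zeros are dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5, 6))$w, 0)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  # tie-free cases match stats::wilcox.test exact p
  set.seed(52)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- sample(1:20, n) * sample(c(-1, 1), n, replace = TRUE)  # distinct magnitudes
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # with ties, exact enumeration is checked against a direct oracle
  d <- c(1, 1, -2, 3, 3, -3, 4, 2)
  ours <- wilcoxon_signed_rank(d)
  r <- rank(abs(d)); w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(0:1), length(d))))
  wplus <- signs %*% r
  p_ref <- mean(pmin(wplus, sum(r) - wplus) <= w_obs + 1e-9)
  expect_equal(ours$p_value, p_ref, tolerance = 1e-12)
})

test_that("Pearson correlation and rater aggregation behave canonically", {
  x <- rnorm(20)
  expect_equal(pearson_corr(x, 2 * x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  y <- rnorm(20)
  expect_equal(pearson_corr(x, y), pearson_corr(3 * x + 1, 0.5 * y - 2))
  expect_error(pearson_corr(x, rep(1, 20)), "variance")

  votes <- rbind(c(1, 1, 1), c(1, 0, 0), c(1, 0, 1), c(1, 0, 1),
                 c(0, 1, 0), c(0, 1, 1))
  agg <- aggregate_raters(votes, seed = 3)
  expect_equal(agg[1], 1L)  # 4 of 6 vote after
  expect_equal(agg[3], 1L)
  # column 2 is a 3-3 tie: resolved by a seeded coin, reproducibly
  expect_identical(aggregate_raters(votes, seed = 3),
                   aggregate_raters(votes, seed = 3))
  single <- matrix(c(1, 0, 1), 1)
  expect_equal(aggregate_raters(single, seed = 1), c(1L, 0L, 1L))
  # over many seeds, ties split roughly evenly
  tie <- matrix(c(1, 0), 2, 1)
  flips <- vapply(1:200, function(s) aggregate_raters(tie, seed = s), integer(1))
  expect_gt(mean(flips), 0.3)
  expect_lt(mean(flips), 0.7)
})
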