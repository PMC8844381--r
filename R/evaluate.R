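#' Evaluation configuration
#'
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param level Confidence level in percent (default 95).
#' @param seed Integer seed for resampling and tie-breaking.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(n_bootstrap = 1000, level = 95, seed = 1L) {
  check_scalar_number(n_bootstrap, "n_bootstrap", positive = TRUE)
  check_scalar_number(level, "level")
  if (level <= 0 || level >= 100) stopf("`level` must lie in (0, 100)")
  check_scalar_number(seed, "seed")
  structure(
    list(n_bootstrap = as.integer(n_bootstrap), level = level,
         seed = as.integer(seed)),
    class = "eval_config"
  )
}

#' Frame-level confusion matrix and derived proportions
#'
#' The positive class is after-onset (label 1). Returns counts and the three
#' headline proportions: accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)` over
#' after-onset frames, specificity `TN/(TN+FP)` over before-onset frames.
#' A ratio with an empty denominator is reported as `NaN` with a warning.
#'
#' @param pred 0/1 predicted labels.
#' @param truth 0/1 annotated labels of the same length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `n`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("`pred` and `truth` lengths differ")
  check_binary(pred, "pred"); check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  n <- length(pred)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: no %s frames", what,
                   if (what == "sensitivity") "after-onset" else "before-onset"))
      return(NaN)
    }
    num / den
  }
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = (tp + tn) / n,
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity")
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, collecting
#' (false positive rate, true positive rate) points, and computes the AUC
#' as the Mann-Whitney concordance probability with ties counted 1/2:
#' the probability that a random after-onset frame scores above a random
#' before-onset frame.
#'
#' @param scores Numeric scores (probability of the after-onset class).
#' @param truth 0/1 labels; both classes must be present.
#' @return A list with `curve` (tibble of `threshold`, `fpr`, `tpr`) and
#'   `auc` (scalar).
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stopf("`scores` and `truth` lengths differ")
  check_binary(truth, "truth")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present in `truth`")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(t) {
    pred <- as.integer(scores >= t)
    tibble(threshold = t,
           fpr = sum(pred == 1 & truth == 0) / n_neg,
           tpr = sum(pred == 1 & truth == 1) / n_pos)
  })
  # Mann-Whitney U with mid-ranks: ties between classes count 1/2.
  r <- rank(scores)
  u <- sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2
  list(curve = curve, auc = u / (n_pos * n_neg))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the items with replacement `n_bootstrap` times, recomputes the
#' statistic on each replicate, and returns the percentile interval at the
#' configured level. Deterministic given the seed in `cfg`.
#'
#' @param x Vector of per-item values (or any list of items).
#' @param statistic Function mapping a resampled vector to a scalar;
#'   default [mean()].
#' @param cfg An [eval_config()].
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' bootstrap_ci(rep(c(1, 0), c(497, 86)), cfg = eval_config(seed = 1))
bootstrap_ci <- function(x, statistic = mean, cfg = eval_config()) {
  n <- length(x)
  if (n < 1) stopf("`x` must be nonempty")
  alpha <- (100 - cfg$level) / 100
  stats_b <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_bootstrap), function(b) {
      statistic(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  qs <- quantile(stats_b, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(lower = qs[1], upper = qs[2])
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' Tests equality of two population proportions with the pooled-variance
#' z statistic `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` where
#' `p = (x1 + x2) / (n1 + n2)`, and a two-sided normal p-value.
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Trial counts (>= 1).
#' @return A one-row tibble with `z`, `p_value`, `p1`, `p2` and a `degenerate`
#'   flag set when the pooled proportion is 0 or 1 (z undefined).
#' @export
#' @examples
#' two_proportion_ztest(80, 100, 60, 100)
two_proportion_ztest <- function(x1, n1, x2, n2) {
  for (v in list(c(x1, n1), c(x2, n2))) {
    if (v[1] < 0 || v[1] > v[2] || v[2] < 1) stopf("need 0 <= x <= n and n >= 1")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(tibble(z = NaN, p_value = NaN, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2,
         degenerate = FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' mid-ranks for ties; the reported statistic is `W = min(W+, W-)`. For
#' `n <= exact_max` nonzero pairs the two-sided p-value is computed by exact
#' enumeration of all `2^n` sign assignments (valid with ties); larger
#' samples use the normal approximation with tie correction.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest n for exact enumeration (default 15).
#' @return A one-row tibble with `w`, `p_value`, `n` (nonzero pairs) and
#'   `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))  # W = 0, p = 0.03125
wilcoxon_signed_rank <- function(d, exact_max = 15) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= exact_max) {
    # Enumerate all sign assignments; p = P(min(W+, W-) <= observed).
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wp <- as.vector(signs %*% r)
    total <- sum(r)
    wmin <- pmin(wp, total - wp)
    p <- mean(wmin <= w + 1e-9)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble(w = w, p_value = min(1, p), n = n, method = method)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Scalar correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` lengths differ")
  if (length(x) < 2) stopf("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance in `x` or `y`")
  cor(x, y, method = "pearson")
}

#' Aggregate multiple raters by per-frame majority vote
#'
#' Each frame's consensus label is the majority over raters; exact ties are
#' resolved by a seeded fair coin, so the aggregate is reproducible.
#'
#' @param votes Matrix of 0/1 labels, raters in rows, frames in columns.
#' @param seed Integer seed for tie-breaking.
#' @return Integer 0/1 vector, one consensus label per frame.
#' @export
#' @examples
#' aggregate_raters(rbind(c(1, 1), c(1, 0), c(0, 0)), seed = 1)
aggregate_raters <- function(votes, seed = 1L) {
  if (!is.matrix(votes)) stopf("`votes` must be a matrix (raters x frames)")
  check_binary(votes, "votes")
  n_raters <- nrow(votes)
  ones <- colSums(votes)
  out <- as.integer(ones * 2 > n_raters)
  tied <- which(ones * 2 == n_raters)
  if (length(tied)) {
    out[tied] <- withr::with_seed(seed,
      as.integer(runif(length(tied)) < 0.5))
  }
  out
}
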