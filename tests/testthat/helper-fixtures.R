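# Shared fixtures and independent oracles, built in code at test time.

# Separable Gaussian blur with edge replication; independent of the
# package's analytic-defocus rendering.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur1 <- function(x) {
    pad_idx <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
    xp <- x[pad_idx, , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) {
      out <- out + k[i] * xp[(i - 1L) + seq_len(nrow(x)), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

# Smooth random texture in [0, 1]
random_texture <- function(n = 64, sigma = 1.2) {
  g <- gauss_blur(matrix(rnorm(n * n), n), sigma)
  (g - min(g)) / (max(g) - min(g))
}

# Two-slice complementary-blur stack: slice A blurred on the left half,
# slice B on the right, with a soft transition.
complementary_blur_pair <- function(gt, sigma = 2.5) {
  n <- ncol(gt)
  ramp <- 1 / (1 + exp(-(seq_len(n) - n / 2) / 3))
  blurred <- gauss_blur(gt, sigma)
  a <- sweep(blurred, 2, 1 - ramp, "*") + sweep(gt, 2, ramp, "*")
  b <- sweep(gt, 2, 1 - ramp, "*") + sweep(blurred, 2, ramp, "*")
  list(a = a, b = b)
}

# Brute-force AUC: concordance over all positive-negative pairs, ties 1/2.
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small labelled texture-class image set: class 1 carries an added
# high-frequency checkerboard, class 0 is smooth noise.
toy_texture_set <- function(n_per_class = 20, size = 64) {
  chk <- outer(seq_len(size), seq_len(size), function(i, j) (-1)^(i + j))
  frames <- list(); labels <- integer()
  for (i in seq_len(n_per_class)) {
    frames[[length(frames) + 1L]] <- matrix(rnorm(size^2, 0, 0.1), size)
    labels <- c(labels, 0L)
    frames[[length(frames) + 1L]] <- chk + matrix(rnorm(size^2, 0, 0.1), size)
    labels <- c(labels, 1L)
  }
  list(frames = frames, labels = labels)
}
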