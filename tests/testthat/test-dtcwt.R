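# The transform must be perfectly invertible and near shift-invariant;
# the quarter-shift filter is validated against its defining design
# properties rather than any stored reference output.

test_that("forward-then-inverse reproduces the input to float precision", {
  set.seed(10)
  for (case in list(c(32, 32, 3), c(64, 64, 4), c(64, 32, 3), c(16, 16, 2))) {
    x <- matrix(rnorm(case[1] * case[2]), case[1], case[2])
    pyr <- dtcwt_forward(x, case[3])
    xr <- dtcwt_inverse(pyr)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-6)
  }
})

test_that("quarter-shift filter satisfies its design properties", {
  h <- polarcall:::.dt_qshift
  # orthonormality: unit energy and vanishing even-lag autocorrelation
  expect_equal(sum(h^2), 1, tolerance = 1e-10)
  ac <- convolve(h, h, type = "open")  # autocorrelation via reversed conv
  center <- (length(ac) + 1) / 2
  even_lags <- ac[center + seq(2, length(h) - 2, by = 2)]
  expect_lt(max(abs(even_lags)), 1e-10)
  # lowpass: unit DC gain in the sqrt(2) normalization
  expect_equal(sum(h), sqrt(2), tolerance = 1e-4)
  # group delay approximates (N-1)/2 + 1/4 over the passband
  n <- seq_along(h) - 1
  omega <- seq(0.05 * pi, 0.4 * pi, length.out = 50)
  gd <- vapply(omega, function(w) {
    H <- sum(h * exp(-1i * w * n))
    Hd <- sum(-1i * n * h * exp(-1i * w * n))
    -Im(Hd / H) * 1  # d(phase)/d(omega) with sign: gd = -d arg H / d w
  }, numeric(1))
  tau <- (length(h) - 1) / 2 + 0.25
  expect_lt(max(abs(gd - tau)), 0.1)
})

test_that("subband energies are stable under a one-pixel shift", {
  set.seed(11)
  x <- gauss_blur(matrix(rnorm(64 * 64), 64), 1)
  p1 <- dtcwt_forward(x, 3)
  xs <- rbind(x[64, ], x[-64, ])  # circular shift by one row
  p2 <- dtcwt_forward(xs, 3)
  for (lev in 2:3) {
    e1 <- sum(vapply(p1$levels[[lev]], function(z) sum(Mod(z)^2), numeric(1)))
    e2 <- sum(vapply(p2$levels[[lev]], function(z) sum(Mod(z)^2), numeric(1)))
    expect_lt(abs(e1 - e2) / e1, 0.12)
  }
})

test_that("dimension and depth constraints are enforced", {
  expect_error(dtcwt_forward(matrix(0, 30, 30), 4), "divisible")
  expect_error(dtcwt_forward(matrix(c(1, NA, 1, 1), 2), 1), "finite")
})
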