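test_that("polarization onset is the first cap fraction at/above threshold", {
  expect_equal(annotate_polarization_onset(c(0.10, 0.20, 0.34, 0.40)), 2L)
  expect_true(is.na(annotate_polarization_onset(c(0.1, 0.2, 0.3))))
  expect_equal(annotate_polarization_onset(c(0.5, 0.1)), 0L)
  # inclusive threshold: exactly 1/3 triggers
  expect_equal(annotate_polarization_onset(c(0, 1 / 3)), 1L)
  expect_error(annotate_polarization_onset(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(annotate_polarization_onset(numeric()), "nonempty")
})

test_that("label_frames builds a single 0-to-1 switch at the onset", {
  expect_equal(label_frames(2, 5), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(label_frames(NA, 3), c(0L, 0L, 0L))
  expect_equal(label_frames(0, 3), c(1L, 1L, 1L))
  expect_equal(label_frames(3, 3), c(0L, 0L, 0L))
  expect_error(label_frames(4, 3), "onset_idx")
  # composition with onset detection is monotone for any series
  set.seed(30)
  for (i in 1:25) {
    s <- runif(sample(3:12, 1))
    lab <- label_frames(annotate_polarization_onset(s), length(s))
    expect_true(all(diff(lab) >= 0))
  }
})

test_that("inter-blastomere angle follows circle-tangent geometry", {
  expect_equal(measure_interblastomere_angle(1, 1, 1), 120, tolerance = 1e-9)
  # limits: point contact -> 0, merged centers -> 180
  expect_lt(measure_interblastomere_angle(1, 1, 1.9999), 2)
  expect_gt(measure_interblastomere_angle(1, 1, 1e-4), 179)
  # closed form for equal radii
  d <- 1.2
  expect_equal(measure_interblastomere_angle(1, 1, d),
               180 - 2 * atan((d / 2) / sqrt(1 - d^2 / 4)) / pi * 180,
               tolerance = 1e-12)
  # strictly decreasing in d
  ds <- seq(0.1, 1.9, by = 0.1)
  a <- vapply(ds, function(d) measure_interblastomere_angle(1, 1, d), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_error(measure_interblastomere_angle(1, 1, 2.5), "intersect")
  expect_error(measure_interblastomere_angle(1, 3, 1.5), "nested")
})

test_that("compaction is called at the first angle strictly above 120", {
  expect_equal(annotate_compaction(c(100, 115, 125, 130)), 2L)
  expect_true(is.na(annotate_compaction(c(100, 120, 120))))  # strict
  expect_equal(annotate_compaction(c(125, 130)), 0L)
  expect_error(annotate_compaction(c(100, 190)), "\\(0, 180\\)")
})

test_that("contour-based angle estimate agrees with the analytic value", {
  draw_circle <- function(n, cy, cx, r) {
    yy <- matrix(seq_len(n), n, n); xx <- t(yy)
    (yy - cy)^2 + (xx - cx)^2 <= r^2
  }
  n <- 301; r <- 90
  for (alpha in c(100, 120, 140)) {
    d <- 2 * r * cos(alpha / 2 * pi / 180)
    m1 <- draw_circle(n, 151, 151 - d / 2, r)
    m2 <- draw_circle(n, 151, 151 + d / 2, r)
    est <- estimate_angle_from_masks(m1, m2, arc_px = 6)
    expect_equal(est, alpha, tolerance = 3)
  }
  expect_error(estimate_angle_from_masks(draw_circle(50, 10, 10, 5),
                                         draw_circle(50, 40, 40, 5)),
               "overlap")
})
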