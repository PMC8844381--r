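test_that("fusing identical or single slices returns the slice", {
  set.seed(20)
  gt <- random_texture(48)
  out1 <- fuse_aif_dtcwt(list(gt))
  expect_lt(max(abs(out1 - gt)) / max(abs(gt)), 1e-6)
  outN <- fuse_aif_dtcwt(list(gt, gt, gt))
  expect_lt(max(abs(outN - gt)) / max(abs(gt)), 1e-6)
})

test_that("complementary-blur fusion beats both slices and their average", {
  set.seed(21)
  wins <- 0L
  for (i in 1:20) {
    gt <- random_texture(64)
    pair <- complementary_blur_pair(gt)
    fused <- fuse_aif_dtcwt(list(pair$a, pair$b))
    r <- c(rmse_f = polarcall:::rmse(fused, gt),
           rmse_a = polarcall:::rmse(pair$a, gt),
           rmse_b = polarcall:::rmse(pair$b, gt),
           rmse_med = polarcall:::rmse((pair$a + pair$b) / 2, gt))
    if (r["rmse_f"] < min(r[-1])) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("fusion is deterministic and honors the lowest-z tie-break", {
  set.seed(22)
  gt <- random_texture(32)
  # identical slices tie on every coefficient: result must equal slice 1
  # and be reproducible across calls
  f1 <- fuse_aif_dtcwt(list(gt, gt + 0))
  f2 <- fuse_aif_dtcwt(list(gt, gt + 0))
  expect_identical(f1, f2)
  expect_lt(max(abs(f1 - gt)), 1e-6 * max(abs(gt)))
  # max_local_energy lowpass rule also runs and returns the right shape
  f3 <- fuse_aif_dtcwt(list(gt, gauss_blur(gt, 2)),
                       fusion_config(lowpass_rule = "max_local_energy"))
  expect_equal(dim(f3), dim(gt))
})

test_that("non-power-of-two shapes are padded and cropped back", {
  set.seed(23)
  gt <- random_texture(50)[, 1:37]
  out <- fuse_aif_dtcwt(list(gt, gauss_blur(gt, 2)))
  expect_equal(dim(out), c(50, 37))
  expect_error(fuse_aif_dtcwt(list(matrix(0, 1, 1))), "too deep")
  expect_error(fuse_aif_dtcwt(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "same shape")
  expect_error(fuse_aif_dtcwt(list()), "at least one")
})

test_that("maximum-intensity projection is an element-wise maximum", {
  s1 <- matrix(c(1, 2, 5, 0), 2)
  s2 <- matrix(c(4, 0, 1, 3), 2)
  expect_equal(max_intensity_projection(list(s1, s2)),
               matrix(c(4, 2, 5, 3), 2))
  expect_equal(max_intensity_projection(list(s2, s1)),
               max_intensity_projection(list(s1, s2)))
  expect_true(all(max_intensity_projection(list(s1 * 0, s2 * 0)) == 0))
  # monotone: raising any input pixel never lowers the output
  s1b <- s1; s1b[2, 1] <- s1b[2, 1] + 10
  expect_true(all(max_intensity_projection(list(s1b, s2)) >=
                    max_intensity_projection(list(s1, s2))))
})

test_that("fuse_recording compresses both channels and keeps timing", {
  out <- generate_recording(synth_config(n_frames = 6, polarization_frame = 3,
                                         compaction_frame = 2, n_z = 3,
                                         img_size = 48, seed = 9))
  fused <- fuse_recording(out$recording)
  expect_s3_class(fused, "fused_sequence")
  expect_length(fused$dic, 6)
  expect_length(fused$fluorescence, 6)
  expect_equal(fused$frame_interval_s, out$recording$frame_interval_s)

  # AIF frames must be at least as sharp as the median z slice, per frame
  d <- dim(out$recording$tensor)
  med <- (d[2] + 1) %/% 2
  for (t in seq_len(d[1])) {
    m <- out$recording$tensor[t, med, 1, , ]; dim(m) <- d[4:5]
    expect_gte(polarcall:::gradient_energy(fused$dic[[t]]),
               polarcall:::gradient_energy(m * 1.0))
  }

  # single z slice: both channels reduce to that slice
  out1 <- generate_recording(synth_config(n_frames = 3, polarization_frame = 1,
                                          compaction_frame = 1, n_z = 1,
                                          img_size = 32, seed = 4))
  f1 <- fuse_recording(out1$recording)
  s <- out1$recording$tensor[2, 1, 2, , ]; dim(s) <- c(32, 32)
  expect_equal(f1$fluorescence[[2]], s)
  sd_ <- out1$recording$tensor[2, 1, 1, , ]; dim(sd_) <- c(32, 32)
  expect_lt(max(abs(f1$dic[[2]] - sd_)) / max(sd_), 1e-6)

  # missing channel role errors
  rec <- out1$recording
  rec$channel_roles <- c(dic = 1)
  expect_error(fuse_recording(rec), "fluorescence")
})
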