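test_that("generation is bit-identical given the seed", {
  cfg <- synth_config(n_frames = 8, compaction_frame = 2,
                      polarization_frame = 4, n_z = 3, img_size = 32, seed = 5)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$tensor, b$recording$tensor)
  expect_identical(a$truth, b$truth)
})

test_that("ground-truth series satisfy the generator invariants", {
  for (seed in c(1, 7, 13)) {
    out <- generate_recording(synth_config(n_frames = 10, compaction_frame = 3,
                                           polarization_frame = 6, n_z = 3,
                                           img_size = 32, seed = seed))
    tr <- out$truth
    expect_true(all(diff(tr$angle_series) >= 0))
    expect_true(all(diff(tr$cap_series) >= 0))
    expect_true(all(diff(tr$labels) >= 0))            # single 0 -> 1 switch
    expect_equal(tr$labels,
                 label_frames(tr$polarization_onset_idx, tr$n_frames))
    expect_gte(tr$frame_interval_s, 1200)
    expect_lte(tr$frame_interval_s, 2400)
    expect_true(all(tr$cap_series >= 0 & tr$cap_series <= 1))
    # cap reaches exactly 1/3 at the configured onset
    expect_equal(tr$cap_series[tr$polarization_onset_idx + 1], 1 / 3)
    expect_lte(tr$compaction_idx, tr$polarization_onset_idx)
  }
})

test_that("measured angle crosses 120 degrees exactly at compaction", {
  out <- generate_recording(synth_config(n_frames = 10, compaction_frame = 4,
                                         polarization_frame = 7, n_z = 3,
                                         img_size = 32, seed = 2))
  cp <- out$truth$critical_pair
  k <- out$truth$compaction_idx
  at <- measure_interblastomere_angle(cp$r[k + 1], cp$r[k + 1], cp$d[k + 1])
  before <- measure_interblastomere_angle(cp$r[k], cp$r[k], cp$d[k])
  expect_gt(at, 120)
  expect_lte(before, 120)
  # and the annotation rules recover both ground-truth indices
  expect_equal(annotate_compaction(out$truth$angle_series), k)
  expect_equal(annotate_polarization_onset(out$truth$cap_series),
               out$truth$polarization_onset_idx)
})

test_that("the DIC polarization cue can be switched off", {
  base <- list(n_frames = 6, compaction_frame = 2, polarization_frame = 3,
               n_z = 1, img_size = 32, noise_sd = 0, seed = 3,
               frame_interval_s = 1800)
  with_cue <- generate_recording(do.call(synth_config, c(base, dic_cue_strength = 1)))
  no_cue <- generate_recording(do.call(synth_config, c(base, dic_cue_strength = 0)))
  dic_w <- with_cue$recording$tensor[, , 1, , , drop = FALSE]
  dic_n <- no_cue$recording$tensor[, , 1, , , drop = FALSE]
  # before onset the channels agree; after onset only the cue differs
  expect_identical(dic_w[1:3, , , , , drop = FALSE],
                   dic_n[1:3, , , , , drop = FALSE])
  expect_gt(max(abs(dic_w[4:6, , , , ] - dic_n[4:6, , , , ])), 0)
  # fluorescence is identical either way (cap lives there regardless)
  expect_identical(with_cue$recording$tensor[, , 2, , , drop = FALSE],
                   no_cue$recording$tensor[, , 2, , , drop = FALSE])
})

test_that("cohorts have distinct ids, jittered onsets, seeded determinism", {
  tmpl <- synth_config(n_frames = 12, compaction_frame = 3,
                       polarization_frame = 6, n_z = 3, img_size = 32)
  co <- generate_cohort(6, tmpl, seed = 31)
  ids <- vapply(co, function(e) e$recording$id, character(1))
  expect_length(unique(ids), 6)
  onsets <- vapply(co, function(e) e$truth$polarization_onset_idx, integer(1))
  intervals <- vapply(co, function(e) e$truth$frame_interval_s, numeric(1))
  expect_gt(length(unique(intervals)), 1)
  expect_true(all(intervals >= 1200 & intervals <= 2400))
  # compaction-to-polarization lag respects min_lag
  lags <- vapply(co, function(e) {
    e$truth$polarization_onset_idx - e$truth$compaction_idx
  }, integer(1))
  expect_true(all(lags >= 3))

  co2 <- generate_cohort(6, tmpl, seed = 31)
  expect_identical(co[[4]]$recording$tensor, co2[[4]]$recording$tensor)
  co3 <- generate_cohort(6, tmpl, seed = 99)
  expect_false(identical(onsets,
                         vapply(co3, function(e) e$truth$polarization_onset_idx,
                                integer(1))) &&
                 identical(intervals,
                           vapply(co3, function(e) e$truth$frame_interval_s,
                                  numeric(1))))

  # a cohort member is regenerable from its echoed configuration
  again <- generate_recording(co[[2]]$cfg)
  expect_identical(again$recording$tensor, co[[2]]$recording$tensor)
  expect_error(generate_cohort(0), ">= 1")
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(compaction_frame = 5, polarization_frame = 3),
               "compaction_frame")
  expect_error(synth_config(polarization_frame = 30, n_frames = 24),
               "n_frames")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(angle_start_deg = 150, angle_end_deg = 120),
               "angle_start_deg")
})
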