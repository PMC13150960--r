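test_that("generated hypnograms start awake, hit the configured N3 share, and repeat under a seed", {
  h <- generate_hypnogram(total_epochs = 960, seed = 1)
  expect_length(unclass(h), 960)
  expect_equal(unclass(h)[1], "W")
  st <- unclass(h)
  sleep <- st[st %in% SLEEP_STAGES]
  # dwell expectation 0.178 frozen from a 100-seed Monte-Carlo run
  expect_lt(abs(mean(sleep == "N3") - 0.178), 0.05)
  expect_identical(unclass(generate_hypnogram(total_epochs = 960, seed = 1)),
                   st)
  # a full cycle appears in a night-length hypnogram
  expect_true(all(c("N1", "N2", "N3", "REM") %in% st))
})

test_that("degenerate parameters give an all-wake hypnogram and bad lengths error", {
  h <- generate_hypnogram(hypnogram_params(wake_start_mean = 50), 10, seed = 0)
  expect_equal(unclass(h), rep("W", 10), ignore_attr = TRUE)
  expect_error(generate_hypnogram(total_epochs = 0), "positive")
})

test_that("the old-group hypnogram halves the N3 share", {
  frac <- function(g) {
    st <- unclass(generate_hypnogram(default_hypnogram_params(g), 960,
                                     seed = 71))
    sl <- st[st %in% SLEEP_STAGES]
    mean(sl == "N3")
  }
  expect_lt(frac("old"), 0.65 * frac("young"))
})

test_that("spindle injection matches its rate and raises sigma-band power", {
  h <- hypnogram(rep("N2", 20))                       # 10 min
  p_on <- dplyr::mutate(default_stage_params("young"),
                        spindle_rate = ifelse(stage == "N2", 2, 0),
                        so_amp = 0, alpha_amp = 0)
  p_off <- dplyr::mutate(p_on, spindle_amp = 0)
  sim_on <- synthesize_night(h, p_on, fs = 100, seed = 72, movement_amp = 0)
  sim_off <- synthesize_night(h, p_off, fs = 100, seed = 72, movement_amp = 0)
  n_true <- nrow(sim_on$ground_truth$spindle_events)
  expect_gt(n_true, 20 - 3 * sqrt(20))               # Poisson(20) +/- 3 sd
  expect_lt(n_true, 20 + 3 * sqrt(20))
  bp <- function(sim) {
    psd <- welch_psd(channel(sim$recording, "EEG1"), 100)
    sum(psd$power[psd$freq_hz >= 12 & psd$freq_hz <= 16])
  }
  expect_gt(bp(sim_on), bp(sim_off))
})

test_that("zero-amplitude events reproduce the background rendering sample for sample", {
  h <- hypnogram(c("W", rep("N2", 4), rep("N3", 4), "REM"))
  p0 <- dplyr::mutate(default_stage_params("young"), so_amp = 0,
                      spindle_amp = 0)
  s1 <- synthesize_night(h, p0, fs = 100, seed = 73)
  s2 <- synthesize_night(h, p0, fs = 100, seed = 73)
  expect_identical(s1$recording$samples, s2$recording$samples)
  # non-zero amplitudes change only where events land
  p1 <- default_stage_params("young")
  s3 <- synthesize_night(h, p1, fs = 100, seed = 73)
  expect_false(identical(s1$recording$samples[1, ], s3$recording$samples[1, ]))
})

test_that("injected slow oscillations are negative-then-positive with bounded counts", {
  h <- hypnogram(rep("N3", 20))
  p <- dplyr::mutate(default_stage_params("young"),
                     so_rate = ifelse(stage == "N3", 5, 0))
  counts <- vapply(1:5, function(s) {
    sim <- synthesize_night(h, p, fs = 100, seed = s, movement_amp = 0)
    gt <- sim$ground_truth$so_events
    # trough precedes peak within each logged event
    x <- bandpass(channel(sim$recording, "EEG1"), 0.5, 1.5, fs = 100)
    for (i in seq_len(min(5, nrow(gt)))) {
      idx <- round(gt$onset_s[i] * 100):round((gt$onset_s[i] + gt$duration_s[i]) * 100)
      expect_lt(which.min(x[idx]), which.max(x[idx]))
    }
    nrow(gt)
  }, numeric(1))
  # oracle band from 20-seed simulation: per-seed 30-75, mean >= 40
  expect_true(all(counts >= 30 & counts <= 75))
  expect_gte(mean(counts), 40)
})

test_that("injected spindle durations stay inside the detector's bounds", {
  h <- hypnogram(rep("N2", 40))
  sim <- synthesize_night(h, default_stage_params("young"), fs = 100,
                          seed = 74, movement_amp = 0)
  durs <- sim$ground_truth$spindle_events$duration_s
  expect_true(all(durs >= 0.5 & durs <= 2.0))
})

test_that("background-only band powers are stable across seeds", {
  p0 <- dplyr::mutate(default_stage_params("young"), so_amp = 0,
                      spindle_amp = 0, alpha_amp = 0)
  rels <- vapply(1:20, function(s) {
    sim <- synthesize_night(hypnogram(rep("N2", 10)), p0, fs = 100,
                            seed = s, movement_amp = 0)
    relative_band_power(welch_psd(channel(sim$recording, "EEG1"),
                                  100))$rel_power
  }, numeric(4))
  expect_true(all(apply(rels, 1, function(v) diff(range(v))) < 0.05))
})

test_that("injected events carry more band energy than the local background (signal/log agreement)", {
  h <- hypnogram(rep("N2", 40))
  sim <- synthesize_night(h, default_stage_params("young"), fs = 100,
                          seed = 75, movement_amp = 0)
  sigma <- bandpass(channel(sim$recording, "EEG1"), 12, 16, fs = 100)
  gt <- sim$ground_truth$spindle_events
  set.seed(76)
  take <- gt[sample(nrow(gt), min(50, nrow(gt))), ]
  ok <- vapply(seq_len(nrow(take)), function(i) {
    idx <- round(take$onset_s[i] * 100):round((take$onset_s[i] + take$duration_s[i]) * 100)
    mean(sigma[idx]^2) > stats::median(sigma^2)
  }, logical(1))
  expect_true(all(ok))
})

test_that("unknown stage labels are named in the error", {
  p <- default_stage_params("young")
  p <- p[p$stage != "REM", ]
  expect_error(synthesize_night(hypnogram(c("W", "REM")), p, fs = 100),
               "REM")
})

test_that("data-loss emulation implements each disposition", {
  rec <- noise_recording(600, fs = 20, seed = 77)
  expect_identical(emulate_data_loss(rec, "usable"), rec)
  empty <- emulate_data_loss(rec, "not_worn")
  expect_equal(ncol(empty$samples), 0)
  bt <- emulate_data_loss(rec, "bluetooth", seed = 2)
  expect_lt(duration_s(bt), 0.61 * duration_s(rec))
  expect_gt(duration_s(bt), 0.09 * duration_s(rec))
  expect_error(emulate_data_loss(rec, "lost_in_mail"), "disposition")
})

test_that("adhesion-corrupted nights always fail the quality gate", {
  rec <- noise_recording(8 * 3600, fs = 20, seed = 78)
  for (s in 1:20) {
    bad <- emulate_data_loss(rec, "poor_reference_adhesion", seed = s)
    expect_false(quality_gate(bad)$keep)
  }
})

test_that("cohort generation writes the full file set deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 2, nights_per_participant = 2,
                      total_epochs = 4, fs = 100, seed = 7)
  m1 <- make_cohort(spec, dir1)
  expect_equal(nrow(m1), 8)
  expect_true(all(m1$disposition == "usable"))
  expect_equal(sum(grepl("\\.edf$", list.files(dir1))), 8)
  expect_equal(sum(grepl("\\.hyp$", list.files(dir1))), 8)
  m2 <- make_cohort(spec, dir2)
  m2$recording_path <- m1$recording_path
  m2$hypnogram_path <- m1$hypnogram_path
  expect_equal(m1, m2)
  f <- list.files(dir1, pattern = "\\.edf$")[1]
  expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                   readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))))
})

test_that("certain loss makes every night unusable in the manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 1, nights_per_participant = 2,
                      total_epochs = 4, fs = 100,
                      loss_probs = c(poor_reference_adhesion = 1), seed = 8)
  m <- make_cohort(spec, dir)
  expect_true(all(m$disposition == "poor_reference_adhesion"))
})

test_that("cohort specs round trip through the YAML config format", {
  spec <- cohort_spec(n_per_group = 2, nights_per_participant = 1,
                      total_epochs = 4, fs = 100,
                      loss_probs = c(bluetooth = 0.25), seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back$group_stage_params, spec$group_stage_params)
  expect_equal(back$loss_probs, spec$loss_probs)
  expect_equal(back$seed, spec$seed)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  expect_equal(make_cohort(spec, d1)$night_seed,
               make_cohort(back, d2)$night_seed)
})
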