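# One injected biphasic SO (negative-then-positive, 0.75 Hz) on a quiet
# background, surrounded by smaller wiggles so the percentile rule has a
# candidate pool to beat.
so_test_signal <- function(fs = 100, seed = 31) {
  set.seed(seed)
  n <- 10 * 30 * fs                              # 10 N2/N3 epochs
  x <- rnorm(n, sd = 3)
  # small distractor oscillations
  for (on in c(20, 60, 100, 140, 180, 220)) {
    tt <- seq(0, 4 / 3, by = 1 / fs)
    x[(on * fs):(on * fs + length(tt) - 1)] <-
      x[(on * fs):(on * fs + length(tt) - 1)] - 15 * sin(2 * pi * 0.75 * tt)
  }
  tt <- seq(0, 4 / 3, by = 1 / fs)
  x[(250 * fs):(250 * fs + length(tt) - 1)] <-
    x[(250 * fs):(250 * fs + length(tt) - 1)] - 75 * sin(2 * pi * 0.75 * tt)
  list(x = x, hyp = hypnogram(rep("N3", 10)), big_onset = 250)
}

test_that("an injected high-amplitude SO is detected at its onset", {
  s <- so_test_signal()
  ev <- detect_slow_oscillations(s$x, s$hyp, fs = 100)
  expect_gt(nrow(ev), 0)
  expect_true(any(abs(ev$onset_s - s$big_onset) < 0.5))
  expect_true(all(ev$kind == "SO"))
})

test_that("the duration rule excludes short and long zero-crossing pairs", {
  # a short transient is smeared to in-band duration by the 0.5-1.5 Hz
  # filter, so the rule is asserted on the detector's own candidate pool:
  # nothing outside [0.5, 2] s may survive into the returned set
  set.seed(32)
  fs <- 100
  x <- rnorm(10 * 30 * fs, sd = 3)
  tt <- seq(0, 0.3, by = 1 / fs)
  x[(100 * fs):(100 * fs + length(tt) - 1)] <- -200 * sin(2 * pi * (1 / 0.3) * tt)
  ev <- detect_slow_oscillations(x, hypnogram(rep("N3", 10)), fs = fs)
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 2))
  pool <- attr(ev, "candidates")
  expect_true(all(pool$duration_s >= 0.5 & pool$duration_s <= 2))
})

test_that("flat or non-NREM signal yields an empty SO list, not an error", {
  flat <- rep(0, 10 * 30 * 100)
  expect_equal(nrow(detect_slow_oscillations(flat, hypnogram(rep("N3", 10)),
                                             fs = 100)), 0)
  s <- so_test_signal()
  wake <- hypnogram(rep("W", 10))
  expect_equal(nrow(detect_slow_oscillations(s$x, wake, fs = 100)), 0)
})

test_that("every returned SO obeys the duration and percentile rules (audit)", {
  h <- hypnogram(rep("N3", 20))
  p <- dplyr::mutate(default_stage_params("young"),
                     so_rate = ifelse(stage == "N3", 5, 0))
  sim <- synthesize_night(h, p, fs = 100, seed = 33, movement_amp = 0)
  ev <- detect_slow_oscillations(sim$recording, h, fs = 100)
  pool <- attr(ev, "candidates")
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 2))
  thr <- stats::quantile(pool$amplitude_uv, 0.75, names = FALSE)
  expect_true(all(ev$amplitude_uv > thr))
  expect_equal(nrow(ev), sum(pool$amplitude_uv > thr))
})

test_that("events never overlap artifact windows", {
  h <- hypnogram(rep("N2", 20))
  sim <- synthesize_night(h, default_stage_params("young"), fs = 100,
                          seed = 34, movement_amp = 0)
  rec <- sim$recording
  rec$samples[, 5001:5500] <- rec$samples[, 5001:5500] * 80   # 50-55 s burst
  mask <- detect_artifacts(rec)
  expect_true(any(mask$flags))
  sp <- artifact_spans(mask)
  for (ev in list(detect_slow_oscillations(rec, h, mask, fs = 100),
                  detect_spindles(rec, h, "N2", mask, fs = 100))) {
    if (!nrow(ev)) next
    overlap <- vapply(seq_len(nrow(ev)), function(i) {
      any(ev$onset_s[i] < sp$end_s & ev$onset_s[i] + ev$duration_s[i] > sp$onset_s)
    }, logical(1))
    expect_false(any(overlap))
  }
})

test_that("spindle bursts are recovered with accurate onsets", {
  h <- hypnogram(rep("N2", 40))
  p <- dplyr::mutate(default_stage_params("young"),
                     spindle_amp = ifelse(stage == "N2", 60, 0),
                     so_amp = 0, alpha_amp = 0)
  sim <- synthesize_night(h, p, fs = 100, seed = 35, movement_amp = 0)
  truth <- sim$ground_truth$spindle_events
  ev <- detect_spindles(sim$recording, h, "N2", fs = 100)
  hits <- vapply(truth$onset_s, function(o) any(abs(ev$onset_s - o) < 0.3),
                 logical(1))
  expect_gt(mean(hits), 0.9)
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 2))
})

test_that("an overlong sigma burst is not returned as a single spindle", {
  set.seed(36)
  fs <- 100
  x <- rnorm(20 * 30 * fs, sd = 3)
  tt <- seq(1 / fs, 2.5, by = 1 / fs)             # 2.5 s burst, too long
  burst <- 60 * sin(2 * pi * 13 * tt)
  x[(100 * fs + 1):(100 * fs + length(burst))] <- x[(100 * fs + 1):(100 * fs + length(burst))] + burst
  ev <- detect_spindles(x, hypnogram(rep("N2", 20)), "N2", fs = fs)
  inside <- ev$onset_s > 99 & ev$onset_s < 103
  expect_false(any(inside & ev$duration_s > 2))
})

test_that("spindle detection is invariant to global amplitude scaling", {
  h <- hypnogram(rep("N2", 20))
  sim <- synthesize_night(h, default_stage_params("young"), fs = 100,
                          seed = 37, movement_amp = 0)
  e1 <- detect_spindles(sim$recording, h, "N2", fs = 100)
  scaled <- sim$recording
  scaled$samples <- scaled$samples * 12.5
  e2 <- detect_spindles(scaled, h, "N2", fs = 100)
  expect_equal(e1$onset_s, e2$onset_s)
  expect_equal(e1$duration_s, e2$duration_s)
})

test_that("densities divide counts by clean minutes and refuse zero denominators", {
  ev30 <- tibble::tibble(onset_s = 1:30)
  expect_equal(so_density(ev30, 60), 0.5)
  expect_equal(so_density(tibble::tibble(onset_s = numeric()), 10), 0)
  expect_equal(spindle_density(12, 10), 1.2)
  expect_error(so_density(ev30, 0), "undefined")
  expect_error(spindle_density(5, 0), "undefined")
})

test_that("spindle density recovers the injected rate within the surviving fraction", {
  # the detection threshold drops weak spindles; the oracle here is the
  # recall measured against ground truth on the same nights
  h <- hypnogram(rep("N2", 40))
  p <- dplyr::mutate(default_stage_params("young"),
                     spindle_amp = ifelse(stage == "N2", 60, 0),
                     spindle_rate = ifelse(stage == "N2", 2, 0),
                     so_amp = 0, alpha_amp = 0)
  dens <- vapply(41:45, function(s) {
    sim <- synthesize_night(h, p, fs = 100, seed = s, movement_amp = 0)
    ev <- detect_spindles(sim$recording, h, "N2", fs = 100)
    truth <- sim$ground_truth$spindle_events
    c(nrow(ev) / 20, nrow(truth) / 20)
  }, numeric(2))
  # detected density within +/-30% of the injected 2/min on average
  expect_lt(abs(mean(dens[1, ]) / 2 - 1), 0.3)
})
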