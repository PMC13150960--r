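test_that("Welch PSD satisfies Parseval for a pure sine", {
  x <- sine_wave(10, 60)
  psd <- welch_psd(x, 100)
  total <- sum(psd$power) * (psd$freq_hz[2] - psd$freq_hz[1])
  expect_lt(abs(total - 0.5), 0.01)                  # sine power = A^2/2
})

test_that("Welch PSD satisfies Parseval for white noise across seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(3000, sd = 2)
    psd <- welch_psd(x, 100)
    total <- sum(psd$power) * (psd$freq_hz[2] - psd$freq_hz[1])
    total / var(x) - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  expect_equal(max(welch_psd(rep(0, 1000), 100)$power), 0)
  expect_error(welch_psd(rnorm(100), 100), "shorter than")
})

test_that("relative band powers sum to one and land in the right band", {
  for (case in list(list(f = 2, band = "delta"), list(f = 10, band = "alpha"))) {
    rel <- relative_band_power(welch_psd(sine_wave(case$f, 60), 100))
    expect_equal(sum(rel$rel_power), 1, tolerance = 1e-9)
    expect_gt(rel$rel_power[rel$band == case$band], 0.95)
  }
  expect_error(relative_band_power(welch_psd(rep(0, 1000), 100)), "zero")
})

test_that("relative band power is invariant to amplitude scaling", {
  set.seed(15)
  x <- rnorm(6000)
  r1 <- relative_band_power(welch_psd(x, 100))
  r2 <- relative_band_power(welch_psd(1234 * x, 100))
  expect_equal(r1$rel_power, r2$rel_power, tolerance = 1e-12)
})

test_that("composite NREM delta is the duration-weighted mean and stays between inputs", {
  expect_equal(composite_nrem_delta(0.6, 0.9, 30, 30), 0.75)
  expect_equal(composite_nrem_delta(0.6, 0.9, 30, 0), 0.6)
  expect_equal(composite_nrem_delta(0.70, 0.88, 300, 60), 0.73)
  set.seed(16)
  for (i in 1:20) {
    d <- sort(runif(2)); m <- runif(2, 1, 100)
    comp <- composite_nrem_delta(d[1], d[2], m[1], m[2])
    expect_gte(comp, d[1]); expect_lte(comp, d[2])
  }
  expect_error(composite_nrem_delta(0.5, 0.5, 0, 0), "undefined")
})

test_that("multitaper spectrogram localises a tone, tracks a chirp, and is flat on white noise", {
  sg <- multitaper_spectrogram(sine_wave(10, 30), fs = 100, step_s = 1)
  peaks <- sg$freq_hz[apply(sg$power, 1, which.max)]
  df <- sg$freq_hz[2] - sg$freq_hz[1]
  expect_true(all(abs(peaks - 10) <= df))
  tt <- seq(1 / 100, 60, by = 1 / 100)
  chirp <- sin(2 * pi * (1 + (15 - 1) * tt / (2 * 60)) * tt)
  sgc <- multitaper_spectrogram(chirp, fs = 100, step_s = 1)
  ridge <- sgc$freq_hz[apply(sgc$power, 1, which.max)]
  expect_gt(cor(seq_along(ridge), ridge, method = "spearman"), 0.95)
  set.seed(17)
  sgw <- multitaper_spectrogram(rnorm(100 * 120), fs = 100, step_s = 1)
  avg_db <- 10 * log10(colMeans(sgw$power))
  sel <- sgw$freq_hz >= 1 & sgw$freq_hz <= 30
  expect_lt(diff(range(avg_db[sel])), 6)             # within +/- 3 dB
  expect_error(multitaper_spectrogram(rnorm(1000), fs = 100, nw = -1),
               "taper")
})

test_that("spectrogram frames over artifact spans are NA", {
  x <- rnorm(100 * 60)
  mask <- clean_mask(60, fs = 100)
  mask$flags[3] <- TRUE                              # seconds 10-15
  sg <- multitaper_spectrogram(x, fs = 100, step_s = 1, mask = mask)
  hit <- sg$time_s > 10 - 3 & sg$time_s < 15 + 3     # frames touching it
  expect_true(any(is.na(sg$power[hit, 1])))
  expect_false(any(is.na(sg$power[!hit, 1])))
})

test_that("delta SNR reproduces constructed power ratios", {
  fs <- 100
  mk_night <- function(amp_sleep, n_w = 4, n_s = 8) {
    n <- (n_w + n_s) * 30 * fs
    x <- sine_wave(2, (n_w + n_s) * 30, fs)
    x[(n_w * 30 * fs + 1):n] <- x[(n_w * 30 * fs + 1):n] * amp_sleep
    list(x = x, hyp = hypnogram(c(rep("W", n_w), rep("N3", n_s))))
  }
  eq <- mk_night(1)
  expect_lt(abs(compute_snr_db(eq$x, eq$hyp, fs = fs)), 1e-6)
  r100 <- mk_night(10)
  expect_equal(compute_snr_db(r100$x, r100$hyp, fs = fs), 20, tolerance = 1e-6)
})

test_that("SNR gains 10 dB when sleep amplitudes grow by sqrt(10), on realistic signal", {
  h <- generate_hypnogram(total_epochs = 120, seed = 21)
  sim <- synthesize_night(h, default_stage_params("young"), fs = 100, seed = 22)
  base <- compute_snr_db(sim$recording, h)
  onset <- match(TRUE, unclass(h) %in% SLEEP_STAGES)
  boosted <- sim$recording
  idx <- ((onset - 1) * 30 * 100 + 1):ncol(boosted$samples)
  boosted$samples[, idx] <- boosted$samples[, idx] * sqrt(10)
  expect_equal(compute_snr_db(boosted, h) - base, 10, tolerance = 0.5)
})

test_that("SNR requires a pre-onset wake baseline", {
  x <- rnorm(100 * 60)
  expect_error(compute_snr_db(x, hypnogram(c("N2", "N2")), fs = 100),
               "pre-onset")
  expect_error(compute_snr_db(x, hypnogram(c("W", "W")), fs = 100),
               "no sleep")
})
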