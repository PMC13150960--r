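#' Canonical EEG frequency bands
#'
#' Delta 0.5--4, theta 4--8, alpha 8--12, beta 12--30 Hz.
#'
#' @return A tibble with `band`, `low_hz`, `high_hz`.
#' @export
default_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low_hz = c(0.5, 4, 8, 12),
    high_hz = c(4, 8, 12, 30)
  )
}

#' Welch power spectral density
#'
#' Hann-tapered, 50%-overlapping segments, mean-averaged, one-sided density
#' in µV²/Hz. The default 4-s window gives 0.25-Hz resolution, enough to
#' resolve the 0.5-Hz lower delta edge.
#'
#' @param x Numeric signal (µV).
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 4).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A `psd` tibble with `freq_hz` and `power` columns; `fs`,
#'   `window_s` and `overlap` stored as attributes.
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  r <- welch_raw(x, fs, window_s, overlap)
  out <- tibble::tibble(freq_hz = r$freq_hz, power = r$power)
  structure(out, fs = fs, window_s = window_s, overlap = overlap,
            class = c("psd", class(out)))
}

# Welch estimate without the tibble wrapper (hot path: per-epoch calls).
welch_raw <- function(x, fs, window_s = 4, overlap = 0.5) {
  x <- as.numeric(x)
  n <- round(window_s * fs)
  if (length(x) < n) {
    stop(sprintf("signal (%d samples) shorter than one %g-s window",
                 length(x), window_s), call. = FALSE)
  }
  step <- max(1, round(n * (1 - overlap)))
  starts <- seq(1, length(x) - n + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # periodic Hann
  scale <- fs * sum(w^2)
  nf <- floor(n / 2) + 1
  # all segments at once: one n x n_seg matrix through mvfft
  seg <- matrix(x[outer(seq_len(n) - 1L, starts, "+")], nrow = n) * w
  sp <- abs(stats::mvfft(seg))^2 / scale
  p <- rowMeans(sp[seq_len(nf), , drop = FALSE])
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq_hz = (seq_len(nf) - 1) * fs / n, power = p * dbl)
}

# Trapezoidal integral of the PSD over [low, high] Hz.
band_power <- function(psd, low, high) {
  f <- psd$freq_hz; p <- psd$power
  keep <- f >= low & f <= high
  if (sum(keep) < 2) return(0)
  fk <- f[keep]; pk <- p[keep]
  sum(diff(fk) * (utils::head(pk, -1) + utils::tail(pk, -1)) / 2)
}

#' Relative band power
#'
#' Band-integrated PSD (trapezoid rule) divided by the summed power across
#' the supplied bands. Fractions sum to one by construction.
#'
#' @param psd A `psd` from [welch_psd()].
#' @param bands A band table as from [default_bands()].
#' @return Tibble with `band`, `power` (µV²) and `rel_power` (fraction).
#' @export
relative_band_power <- function(psd, bands = default_bands()) {
  pw <- purrr::map2_dbl(bands$low_hz, bands$high_hz,
                        function(lo, hi) band_power(psd, lo, hi))
  total <- sum(pw)
  if (total <= 0) {
    stop("total band power is zero; relative power undefined", call. = FALSE)
  }
  tibble::tibble(band = bands$band, power = pw, rel_power = pw / total)
}

#' Duration-weighted composite NREM relative delta power
#'
#' Combines the N2 and N3 relative delta fractions into a single NREM
#' slow-wave-activity index, weighting each stage by the minutes spent in
#' it.
#'
#' @param rel_delta_n2,rel_delta_n3 Relative delta fractions for N2 and N3.
#' @param minutes_n2,minutes_n3 Minutes of (artifact-free) N2 and N3.
#' @return Weighted fraction in `[min(d2,d3), max(d2,d3)]`.
#' @export
composite_nrem_delta <- function(rel_delta_n2, rel_delta_n3,
                                 minutes_n2, minutes_n3) {
  if (minutes_n2 < 0 || minutes_n3 < 0) stop("minutes must be >= 0", call. = FALSE)
  if (minutes_n2 + minutes_n3 == 0) {
    stop("no NREM minutes; composite delta undefined", call. = FALSE)
  }
  if (minutes_n3 == 0) return(rel_delta_n2)
  if (minutes_n2 == 0) return(rel_delta_n3)
  (rel_delta_n2 * minutes_n2 + rel_delta_n3 * minutes_n3) /
    (minutes_n2 + minutes_n3)
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal formulation; returns n x k matrix of unit-norm tapers.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t_ <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  off <- t_[-1] * (n - t_[-1]) / 2
  m <- matrix(0, n, n)
  diag(m) <- diag_main
  m[cbind(seq_len(n - 1), seq(2, n))] <- off
  m[cbind(seq(2, n), seq_len(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    v <- tapers[, j]
    if (j %% 2 == 1) {
      if (sum(v) < 0) tapers[, j] <- -v
    } else {
      if (sum(v * t_) < 0) tapers[, j] <- -v
    }
  }
  tapers
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power estimates with Slepian (DPSS) tapers,
#' averaged across eigenspectra — the standard full-night QC display for
#' sleep EEG. Defaults: 6-s window, 0.25-s step, time-halfbandwidth 3,
#' 5 tapers. Windows overlapping flagged artifact spans are set to `NA`.
#'
#' @param x A `recording` (channel `channel` is used) or numeric vector.
#' @param fs Sampling rate (vector input only).
#' @param channel Channel to display when `x` is a recording.
#' @param window_s,step_s Window length and hop in seconds.
#' @param nw Time-halfbandwidth product.
#' @param k Number of tapers (default `2*nw - 1`).
#' @param mask Optional `artifact_mask`; overlapped windows become `NA`.
#' @param max_freq_hz Truncate the frequency axis (default 40 Hz).
#' @return A `spectrogram`: list with `time_s`, `freq_hz`, `power`
#'   (time x freq, µV²/Hz) and taper parameters.
#' @export
multitaper_spectrogram <- function(x, fs = NULL, channel = "EEG1",
                                   window_s = 6, step_s = 0.25,
                                   nw = 3, k = 2 * nw - 1, mask = NULL,
                                   max_freq_hz = 40) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- channel(x, channel)
  }
  if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  if (nw <= 0 || k < 1 || k > 2 * nw) stop("invalid taper parameters", call. = FALSE)
  n <- round(window_s * fs)
  if (length(x) < n) stop("signal shorter than one spectrogram window", call. = FALSE)
  step <- max(1, round(step_s * fs))
  tap <- dpss_tapers(n, nw, k)
  starts <- seq(1, length(x) - n + 1, by = step)
  nf <- floor(n / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / n
  fkeep <- freqs <= max_freq_hz
  pow <- matrix(NA_real_, nrow = length(starts), ncol = sum(fkeep))
  t0 <- (starts - 1) / fs
  excl <- if (is.null(mask)) rep(FALSE, length(starts)) else {
    overlaps_artifact(mask, t0, t0 + window_s)
  }
  for (i in seq_along(starts)) {
    if (excl[i]) next
    seg <- x[starts[i]:(starts[i] + n - 1)]
    acc <- numeric(nf)
    for (j in seq_len(k)) {
      sp <- abs(stats::fft(seg * tap[, j]))^2 / fs
      acc <- acc + sp[seq_len(nf)]
    }
    one <- acc / k
    dbl <- rep(2, nf); dbl[1] <- 1
    if (n %% 2 == 0) dbl[nf] <- 1
    pow[i, ] <- (one * dbl)[fkeep]
  }
  structure(
    list(time_s = t0 + window_s / 2, freq_hz = freqs[fkeep], power = pow,
         taper_params = list(nw = nw, k = k, window_s = window_s,
                             step_s = step_s)),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d freqs (nw=%g, k=%d, %g-s window)\n",
              length(x$time_s), length(x$freq_hz), x$taper_params$nw,
              x$taper_params$k, x$taper_params$window_s))
  invisible(x)
}

#' Delta-band signal-to-noise ratio of a night
#'
#' Contrasts delta (0.5--4 Hz) power during sleep against the pre-onset
#' wake baseline:
#' `SNR = 10 log10(mean sleep delta power / mean pre-onset wake delta power)`,
#' where sleep onset is the first epoch scored anything other than `W` and
#' epoch-level delta power comes from Welch PSDs of artifact-free 30-s
#' epochs.
#'
#' @param x A `recording` (channel `channel`) or numeric vector.
#' @param hyp A `hypnogram` aligned to the recording.
#' @param mask Optional `artifact_mask`; flagged epochs are excluded.
#' @param fs Sampling rate (vector input only).
#' @param channel Channel used (default the staging channel `EEG1`).
#' @return SNR in dB.
#' @export
compute_snr_db <- function(x, hyp, mask = NULL, fs = NULL, channel = "EEG1") {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- channel(x, channel)
  }
  if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  stages <- unclass(hyp)
  onset <- match(TRUE, stages %in% SLEEP_STAGES)
  if (is.na(onset)) stop("no sleep epochs; SNR undefined", call. = FALSE)
  if (onset == 1) {
    stop("no pre-onset wake epochs; delta SNR baseline undefined", call. = FALSE)
  }
  wake_idx <- which(stages[seq_len(onset - 1)] == "W")
  sleep_idx <- which(stages %in% SLEEP_STAGES & seq_along(stages) >= onset)
  if (!is.null(mask)) {
    wake_idx <- wake_idx[epoch_is_clean(mask, wake_idx)]
    sleep_idx <- sleep_idx[epoch_is_clean(mask, sleep_idx)]
  }
  if (!length(wake_idx) || !length(sleep_idx)) {
    stop("no artifact-free epochs on one side of sleep onset; SNR undefined",
         call. = FALSE)
  }
  epl <- round(30 * fs)
  # batched per-epoch Welch delta power: one FFT over all segments
  epoch_delta <- function(epochs) {
    epochs <- epochs[epochs * epl <= length(x)]
    if (!length(epochs)) return(numeric())
    n <- round(4 * fs); step <- n / 2
    rel_starts <- seq(1, epl - n + 1, by = step)
    starts <- as.vector(outer(rel_starts, (epochs - 1) * epl, "+"))
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
    seg <- matrix(x[outer(seq_len(n) - 1L, starts, "+")], nrow = n) * w
    sp <- abs(stats::mvfft(seg))^2 / (fs * sum(w^2))
    freqs <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
    keep <- freqs >= 0.5 & freqs <= 4
    # one-sided doubling (no DC/Nyquist in the delta band)
    bp_seg <- colSums(2 * sp[which(keep), , drop = FALSE]) -
      colSums(sp[range(which(keep)), , drop = FALSE])  # trapezoid ends half
    bp_seg <- bp_seg * (fs / n)
    colMeans(matrix(bp_seg, nrow = length(rel_starts)))
  }
  dw <- epoch_delta(wake_idx)
  ds <- epoch_delta(sleep_idx)
  10 * log10(mean(ds) / mean(dw))
}
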