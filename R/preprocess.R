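#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and an effective
#' 8th-order magnitude response. Standard quality-control band for the raw
#' patch signal is 0.3--35 Hz; staging uses 0.1--40 Hz.
#'
#' @param x A `recording` or a numeric vector.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs Sampling rate (only needed when `x` is a vector).
#' @param order Filter order per pass (default 4).
#' @return Filtered object of the same type as `x`.
#' @export
bandpass <- function(x, low, high, fs = NULL, order = 4) {
  apply_filter(x, fs, function(sig, rate) {
    if (!(low > 0 && low < high && high < rate / 2)) {
      stop(sprintf("band [%g, %g] Hz must lie inside (0, fs/2 = %g) Hz",
                   low, high, rate / 2), call. = FALSE)
    }
    bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
    zero_phase(bf, sig, npad = round(6 * rate / low))
  })
}

# Forward-backward application of an ARMA filter through the compiled
# kernel; npad reflection samples absorb the start-up transient (longest
# for low cutoff frequencies).
zero_phase <- function(bf, sig, npad) {
  .zp_filter_cpp(as.numeric(bf$b), as.numeric(bf$a), as.numeric(sig),
                 as.integer(npad))
}

#' Zero-phase notch (band-stop) filter for power-line noise
#'
#' Removes the 59--61 Hz mains band with a zero-phase Butterworth
#' band-stop. Only meaningful before downsampling: at 100 Hz the mains
#' band is beyond Nyquist and the call errors with advice to skip it.
#'
#' @inheritParams bandpass
#' @param low,high Stop-band edges in Hz (defaults 59 and 61).
#' @param order Filter order per pass (default 2; steeper orders ring on a
#'   2 Hz-wide stop band).
#' @return Filtered object of the same type as `x`.
#' @export
notch <- function(x, low = 59, high = 61, fs = NULL, order = 2) {
  apply_filter(x, fs, function(sig, rate) {
    if (high >= rate / 2) {
      stop(sprintf(paste0("notch band [%g, %g] Hz is at or beyond Nyquist ",
                          "(%g Hz); skip the notch after downsampling"),
                   low, high, rate / 2), call. = FALSE)
    }
    bf <- signal::butter(order, c(low, high) / (rate / 2), type = "stop")
    zero_phase(bf, sig, npad = round(2 * rate))
  })
}

# Shared dispatcher: run `fn(signal, fs)` over a vector or every channel of
# a recording.
apply_filter <- function(x, fs, fn) {
  if (inherits(x, "recording")) {
    out <- x
    for (i in seq_len(nrow(x$samples))) {
      out$samples[i, ] <- fn(x$samples[i, ], rate = x$fs)
    }
    return(out)
  }
  if (is.null(fs)) stop("`fs` is required when filtering a plain vector", call. = FALSE)
  fn(as.numeric(x), fs)
}

#' Band-limited downsampling
#'
#' Fourier-method resampling: the spectrum is truncated at the target
#' Nyquist frequency and inverse-transformed at the new rate, giving exact
#' anti-aliasing and unit passband gain. Upsampling is refused: the
#' pipeline only ever reduces 250 Hz to the 100 Hz staging rate.
#'
#' @param x A `recording` or numeric vector.
#' @param target_fs Target rate in Hz (must not exceed the current rate).
#' @param fs Current rate (vector input only).
#' @return Resampled object of the same type as `x`.
#' @export
resample_to <- function(x, target_fs = 100, fs = NULL) {
  rate <- if (inherits(x, "recording")) x$fs else fs
  if (is.null(rate)) stop("`fs` is required for a plain vector", call. = FALSE)
  if (target_fs > rate) {
    stop(sprintf("upsampling (%g -> %g Hz) is not supported", rate, target_fs),
         call. = FALSE)
  }
  if (target_fs == rate) return(x)
  if (inherits(x, "recording")) {
    n_out <- floor(ncol(x$samples) * target_fs / rate)
    out <- x
    samples <- matrix(0, nrow = nrow(x$samples), ncol = n_out)
    rownames(samples) <- x$channel_labels
    for (i in seq_len(nrow(x$samples))) {
      samples[i, ] <- resample_fft(x$samples[i, ], n_out)
    }
    out$samples <- samples
    out$fs <- target_fs
    return(out)
  }
  resample_fft(as.numeric(x), floor(length(x) * target_fs / rate))
}

# Spectrum-truncation resampling to exactly n_out samples.
resample_fft <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  nh <- floor(min(n, n_out) / 2)
  Y[1] <- X[1]
  if (nh >= 2) {
    Y[2:nh] <- X[2:nh]
    Y[n_out - (2:nh) + 2] <- X[n - (2:nh) + 2]
  }
  if (n_out %% 2 == 0 && nh >= 1 && n_out < n) {
    # fold the two old bins that alias onto the new Nyquist bin
    Y[nh + 1] <- (X[nh + 1] + X[n - nh + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Windowed interchannel-covariance artifact detection
#'
#' The recording is cut into consecutive non-overlapping windows (5 s by
#' default; a trailing partial window is dropped). For each window a single
#' scalar metric is computed: `log(eps + mean over channel pairs of
#' |covariance|)`. The metric is z-scored across all windows of the
#' recording, and windows with |z| above the threshold (3 by default) are
#' flagged as artifact. The log makes the metric scale-robust — a global
#' gain change shifts every window equally and leaves z untouched — and maps
#' both flatline (covariance collapses toward `eps`) and movement bursts
#' (covariance explodes) to large |z|.
#'
#' @param x A `recording` with at least two channels.
#' @param window_s Window length in seconds (default 5).
#' @param z_threshold Flag threshold on |z| (default 3).
#' @param eps Floor inside the log (default 1e-12).
#' @return An `artifact_mask`: list with `window_s`, `flags` (logical per
#'   window), `zscores`, `metric` and the recording's `fs`.
#' @export
detect_artifacts <- function(x, window_s = 5, z_threshold = 3, eps = 1e-12) {
  stopifnot(inherits(x, "recording"))
  if (nrow(x$samples) < 2) stop("artifact detection needs >= 2 channels", call. = FALSE)
  wlen <- round(window_s * x$fs)
  n_win <- floor(ncol(x$samples) / wlen)
  if (n_win < 2) stop("recording shorter than two artifact windows", call. = FALSE)
  pairs <- utils::combn(nrow(x$samples), 2)
  keep <- seq_len(n_win * wlen)
  # per-window pairwise covariances via column means of reshaped products
  wmean <- function(v) colMeans(matrix(v[keep], nrow = wlen))
  mu <- apply(x$samples, 1, wmean)                  # n_win x n_chan
  sum_abs_cov <- 0
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cij <- wmean(x$samples[i, ] * x$samples[j, ]) - mu[, i] * mu[, j]
    sum_abs_cov <- sum_abs_cov + abs(cij * wlen / (wlen - 1))
  }
  metric <- log(eps + sum_abs_cov / ncol(pairs))
  s <- stats::sd(metric)
  z <- if (is.na(s) || s == 0) rep(0, n_win) else (metric - mean(metric)) / s
  structure(
    list(window_s = window_s, flags = abs(z) > z_threshold,
         zscores = z, metric = metric, fs = x$fs),
    class = "artifact_mask"
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d windows of %g s, %d flagged (%.1f%%)\n",
              length(x$flags), x$window_s, sum(x$flags),
              100 * mean(x$flags)))
  invisible(x)
}

#' An all-clean artifact mask for a given duration
#' @param duration_s Recording duration in seconds.
#' @param window_s Window length (default 5 s).
#' @param fs Sampling rate recorded on the mask.
#' @return An `artifact_mask` with no windows flagged.
#' @export
clean_mask <- function(duration_s, window_s = 5, fs = 100) {
  n <- floor(duration_s / window_s)
  structure(list(window_s = window_s, flags = rep(FALSE, n),
                 zscores = rep(0, n), metric = rep(0, n), fs = fs),
            class = "artifact_mask")
}

#' Time spans flagged as artifact
#' @param mask An `artifact_mask`.
#' @return Tibble with `onset_s` and `end_s` of each flagged window.
#' @export
artifact_spans <- function(mask) {
  w <- which(mask$flags)
  tibble::tibble(onset_s = (w - 1) * mask$window_s, end_s = w * mask$window_s)
}

# TRUE where [t0, t1) overlaps any flagged window.
overlaps_artifact <- function(mask, t0, t1) {
  if (!any(mask$flags)) return(rep(FALSE, length(t0)))
  cf <- c(0, cumsum(mask$flags))
  nw <- length(mask$flags)
  w0 <- pmax(pmin(floor(t0 / mask$window_s), nw - 1), 0)
  w1 <- pmax(pmin(ceiling(t1 / mask$window_s) - 1, nw - 1), 0)
  ok <- w1 >= w0
  out <- rep(FALSE, length(t0))
  out[ok] <- (cf[w1[ok] + 2] - cf[w0[ok] + 1]) > 0
  out
}

# Fraction of an epoch [on, on+30) covered by flagged windows; used to count
# artifact-free minutes. Windows are wholly in or out of an epoch when
# 30 %% window_s == 0 (the default).
epoch_is_clean <- function(mask, epoch_idx) {
  wpe <- 30 / mask$window_s
  vapply(epoch_idx, function(e) {
    w0 <- floor((e - 1) * wpe) + 1
    w1 <- min(ceiling(e * wpe), length(mask$flags))
    if (w0 > length(mask$flags)) return(TRUE)
    !any(mask$flags[w0:w1])
  }, logical(1))
}

#' Recording-level quality gate
#'
#' A night is kept when at least 5 hours of signal were actually recorded,
#' or — for shorter files — when wrist actigraphy independently reports
#' under 5 hours of total sleep, in which case the short file is taken at
#' face value rather than as a device failure. "Recorded time" excludes
#' dead signal: flatlined 5-s windows (near-zero range on every channel,
#' the signature of a detached reference electrode) and, when an artifact
#' mask is supplied, its flagged windows.
#'
#' @param x A `recording`, or a duration in minutes.
#' @param mask Optional `artifact_mask`; flagged windows do not count as
#'   recorded time.
#' @param actigraphy_tst_min Optional actigraphy total-sleep-time (minutes).
#' @param flat_tol Peak-to-peak range (µV) under which a window counts as
#'   flatlined.
#' @return A tibble with `keep` (logical), `reason` (one of `ok`,
#'   `short_recording`, `short_but_actigraphy_concordant`) and
#'   `duration_min` (recorded minutes after exclusions).
#' @export
quality_gate <- function(x, mask = NULL, actigraphy_tst_min = NULL,
                         flat_tol = 1e-6) {
  if (inherits(x, "recording")) {
    wlen <- round(5 * x$fs)
    n_win <- floor(ncol(x$samples) / wlen)
    dead <- rep(TRUE, n_win)
    if (n_win > 0) {
      keep <- seq_len(n_win * wlen)
      for (ch in seq_len(nrow(x$samples))) {
        m <- matrix(x$samples[ch, keep], nrow = wlen)
        v <- colMeans(m^2) - colMeans(m)^2           # per-window variance
        dead <- dead & v < (flat_tol / 2)^2
      }
    }
    if (!is.null(mask) && length(mask$flags) == n_win) {
      dead <- dead | mask$flags
    }
    tail_min <- (ncol(x$samples) - n_win * wlen) / x$fs / 60
    dur_min <- sum(!dead) * 5 / 60 + tail_min
  } else {
    dur_min <- as.numeric(x)
  }
  if (dur_min >= 300) {
    reason <- "ok"; keep <- TRUE
  } else if (!is.null(actigraphy_tst_min) && !is.na(actigraphy_tst_min) &&
             actigraphy_tst_min < 300) {
    reason <- "short_but_actigraphy_concordant"; keep <- TRUE
  } else {
    reason <- "short_recording"; keep <- FALSE
  }
  tibble::tibble(keep = keep, reason = reason, duration_min = dur_min)
}
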