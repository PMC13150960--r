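#' Default slow-oscillation and spindle detector parameters
#'
#' @return Named list: `so_band` (0.5--1.5 Hz), `so_amp_percentile` (75),
#'   `spindle_band` (12--16 Hz), `rms_window_s` (0.3), `rms_step_s` (0.1),
#'   `rms_threshold_sd` (1.5), `duration_bounds_s` (0.5--2).
#' @export
detector_params <- function() {
  list(
    so_band = c(0.5, 1.5),
    so_amp_percentile = 75,
    spindle_band = c(12, 16),
    rms_window_s = 0.3,
    rms_step_s = 0.1,
    rms_threshold_sd = 1.5,
    duration_bounds_s = c(0.5, 2.0)
  )
}

empty_events <- function() {
  tibble::tibble(kind = character(), onset_s = numeric(),
                 duration_s = numeric(), amplitude_uv = numeric(),
                 stage = character(), channel = character())
}

# Minutes of artifact-free time within epochs of the given stage(s),
# counted in whole artifact windows (5 s by default).
clean_stage_minutes <- function(hyp, mask, stages) {
  st <- unclass(hyp)
  idx <- which(st %in% stages)
  if (!length(idx)) return(0)
  if (is.null(mask) || !any(mask$flags)) return(length(idx) * 0.5)
  wpe <- 30 / mask$window_s
  clean_windows <- 0
  for (e in idx) {
    w0 <- floor((e - 1) * wpe) + 1
    w1 <- min(e * wpe, length(mask$flags))
    if (w0 > length(mask$flags)) {
      clean_windows <- clean_windows + wpe
    } else {
      clean_windows <- clean_windows + sum(!mask$flags[w0:w1]) +
        max(0, e * wpe - length(mask$flags))
    }
  }
  clean_windows * mask$window_s / 60
}

#' Detect slow oscillations by zero-crossing and amplitude-percentile rules
#'
#' The staging-channel signal is band-passed to 0.5--1.5 Hz (zero phase).
#' Every pair of consecutive down-going zero crossings that brackets a
#' negative half-wave followed by a positive half-wave is a candidate.
#' Candidates are kept when (1) the time between the bounding
#' down-crossings is 0.5--2 s, (2) the candidate lies wholly within NREM
#' epochs and overlaps no artifact window, and (3) its peak-to-peak
#' amplitude (positive peak minus negative trough) exceeds the 75th
#' percentile of all candidate amplitudes of that night. The full candidate
#' pool is attached as attribute `candidates` so the percentile rule can be
#' audited.
#'
#' @param x A `recording` (channel `channel` used) or numeric vector.
#' @param hyp A `hypnogram` aligned to the signal.
#' @param mask Optional `artifact_mask`.
#' @param fs Sampling rate (vector input only).
#' @param channel Detection channel (default `EEG1`).
#' @param params Detector parameters, see [detector_params()].
#' @return Tibble of events (`kind = "SO"`, `onset_s`, `duration_s`,
#'   `amplitude_uv` peak-to-peak, `stage`, `channel`), with the candidate
#'   pool in `attr(, "candidates")`.
#' @export
detect_slow_oscillations <- function(x, hyp, mask = NULL, fs = NULL,
                                     channel = "EEG1",
                                     params = detector_params()) {
  chan_name <- channel
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- channel(x, chan_name)
  }
  if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  stages <- unclass(hyp)
  if (!any(stages %in% NREM_STAGES)) {
    out <- empty_events()
    attr(out, "candidates") <- out
    return(out)
  }
  sig <- bandpass(x, params$so_band[1], params$so_band[2], fs = fs)
  # down-going zero crossings: sample >= 0 followed by sample < 0
  dc <- which(sig[-length(sig)] >= 0 & sig[-1] < 0)
  if (length(dc) < 2) {
    out <- empty_events(); attr(out, "candidates") <- out; return(out)
  }
  nc <- length(dc) - 1
  ok <- logical(nc); amp <- numeric(nc)
  up <- sig[-length(sig)] < 0 & sig[-1] >= 0
  cum_up <- cumsum(up)
  for (i in seq_len(nc)) {
    a <- dc[i]; b <- dc[i + 1]
    span <- sig[(a + 1):b]
    # a negative half-wave then a positive half-wave: an up-crossing
    # strictly inside the span
    if (cum_up[b - 1] - cum_up[a] > 0 && any(span > 0) && any(span < 0)) {
      ok[i] <- TRUE
      amp[i] <- max(span) - min(span)
    }
  }
  onset <- dc[seq_len(nc)][ok] / fs
  cands <- tibble::tibble(
    kind = "SO", onset_s = onset,
    duration_s = (dc[-1][ok] - dc[seq_len(nc)][ok]) / fs,
    amplitude_uv = amp[ok],
    stage = stage_at(hyp, onset), channel = chan_name
  )
  if (!nrow(cands)) {
    out <- empty_events(); attr(out, "candidates") <- out; return(out)
  }
  end_stage <- stage_at(hyp, cands$onset_s + cands$duration_s - 1e-9)
  in_nrem <- cands$stage %in% NREM_STAGES & end_stage %in% NREM_STAGES
  cands <- cands[in_nrem, , drop = FALSE]
  if (nrow(cands) && !is.null(mask)) {
    bad <- overlaps_artifact(mask, cands$onset_s, cands$onset_s + cands$duration_s)
    cands <- cands[!bad, , drop = FALSE]
  }
  if (!nrow(cands)) {
    out <- empty_events(); attr(out, "candidates") <- out; return(out)
  }
  dur_ok <- cands$duration_s >= params$duration_bounds_s[1] &
    cands$duration_s <= params$duration_bounds_s[2]
  pool <- cands[dur_ok, , drop = FALSE]
  if (!nrow(pool)) {
    out <- empty_events(); attr(out, "candidates") <- pool; return(out)
  }
  thr <- stats::quantile(pool$amplitude_uv, params$so_amp_percentile / 100,
                         names = FALSE)
  out <- pool[pool$amplitude_uv > thr, , drop = FALSE]
  attr(out, "candidates") <- pool
  attr(out, "amplitude_threshold_uv") <- thr
  out
}

# Sliding-window RMS of a signal: window `w` samples every `step` samples.
# Returns list(t0 = window start times in s, rms).
sliding_rms <- function(sig, fs, window_s, step_s) {
  w <- round(window_s * fs)
  step <- round(step_s * fs)
  n <- length(sig)
  if (n < w) return(list(t0 = numeric(), rms = numeric()))
  cs <- c(0, cumsum(sig^2))
  starts <- seq(1, n - w + 1, by = step)
  rms <- sqrt((cs[starts + w] - cs[starts]) / w)
  list(t0 = (starts - 1) / fs, rms = rms)
}

#' Detect sleep spindles by sliding-window RMS thresholding
#'
#' The signal is band-passed to 12--16 Hz (zero phase) and its RMS computed
#' in 0.3-s windows sliding in 0.1-s steps. Windows lying wholly within
#' artifact-free epochs of the requested stage enter the night's
#' statistics; the detection threshold is the mean of those RMS values
#' plus `rms_threshold_sd` (1.5) standard deviations of the band-passed
#' signal over the same epochs. Both statistics scale linearly with the
#' signal, so detection is invariant to global gain; and because the
#' signal's SD — not the SD of the heavily smoothed RMS series — sets the
#' spread, background noise rarely sustains a spindle-length excursion
#' above threshold.
#' A spindle is a maximal run of eligible suprathreshold windows whose span
#' (first window start to last window end) lasts 0.5--2 s. Runs may cross
#' boundaries between contiguous epochs of the same stage; a subthreshold
#' dip splits runs. Event amplitude is the maximum RMS within the run.
#'
#' @inheritParams detect_slow_oscillations
#' @param stage Which stage's epochs to scan: `"N2"` or `"N3"`.
#' @param sigma_signal Optional precomputed sigma-band (12--16 Hz)
#'   filtered signal, to avoid re-filtering when detecting in both stages.
#' @return Tibble of events (`kind = "spindle"`, `amplitude_uv` = peak RMS).
#' @export
detect_spindles <- function(x, hyp, stage = "N2", mask = NULL, fs = NULL,
                            channel = "EEG1", params = detector_params(),
                            sigma_signal = NULL) {
  chan_name <- channel
  stopifnot(stage %in% c("N2", "N3"))
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- channel(x, chan_name)
  }
  if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  stages <- unclass(hyp)
  if (!any(stages == stage)) return(empty_events())
  sig <- if (is.null(sigma_signal)) {
    bandpass(x, params$spindle_band[1], params$spindle_band[2], fs = fs)
  } else {
    sigma_signal
  }
  r <- sliding_rms(sig, fs, params$rms_window_s, params$rms_step_s)
  if (!length(r$rms)) return(empty_events())
  t1 <- r$t0 + params$rms_window_s
  e0 <- floor(r$t0 / 30) + 1
  e1 <- floor((t1 - 1e-9) / 30) + 1
  in_stage <- stages[pmin(e0, length(stages))] == stage &
    stages[pmin(e1, length(stages))] == stage & e1 <= length(stages)
  eligible <- in_stage
  if (!is.null(mask) && any(mask$flags)) {
    eligible <- eligible & !overlaps_artifact(mask, r$t0, t1)
  }
  if (!any(eligible)) return(empty_events())
  # signal SD over the eligible (artifact-free, in-stage) epochs
  epl <- round(30 * fs)
  elig_ep <- sort(unique(e0[eligible]))
  sig_idx <- unlist(lapply(elig_ep, function(e) {
    ((e - 1) * epl + 1):min(e * epl, length(sig))
  }))
  mu <- mean(r$rms[eligible])
  sdv <- stats::sd(sig[sig_idx])
  if (is.na(sdv)) return(empty_events())
  thr <- mu + params$rms_threshold_sd * sdv
  hit <- eligible & r$rms > thr
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- purrr::map_dfr(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- t1[i1] - r$t0[i0]
    if (dur < params$duration_bounds_s[1] || dur > params$duration_bounds_s[2]) {
      return(NULL)
    }
    tibble::tibble(
      kind = "spindle", onset_s = r$t0[i0], duration_s = dur,
      amplitude_uv = max(r$rms[i0:i1]), stage = stage, channel = chan_name
    )
  })
  if (!nrow(out)) return(empty_events())
  attr(out, "rms_threshold_uv") <- thr
  out
}

#' Slow-oscillation density
#'
#' Detected SO count divided by artifact-free NREM minutes.
#'
#' @param events Event tibble from [detect_slow_oscillations()] (or a count).
#' @param nrem_minutes_clean Artifact-free NREM minutes (> 0).
#' @return Events per minute.
#' @export
so_density <- function(events, nrem_minutes_clean) {
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (nrem_minutes_clean <= 0) {
    stop("zero NREM minutes; density undefined", call. = FALSE)
  }
  n / nrem_minutes_clean
}

#' Spindle density
#'
#' Detected spindle count divided by artifact-free minutes of the stage
#' they were detected in.
#'
#' @param events Event tibble from [detect_spindles()] (or a count).
#' @param stage_minutes_clean Artifact-free minutes of the stage (> 0).
#' @return Events per minute.
#' @export
spindle_density <- function(events, stage_minutes_clean) {
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (stage_minutes_clean <= 0) {
    stop("zero stage minutes; density undefined", call. = FALSE)
  }
  n / stage_minutes_clean
}
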