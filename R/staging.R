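#' Align an on-disk hypnogram to a recording
#'
#' The supported staging path: stages scored elsewhere are read from file
#' and aligned to the recording's 30-s epoch grid. A hypnogram one epoch
#' short is padded with `UNSCORED`; one epoch long is truncated with a
#' warning; any larger mismatch is an alignment error.
#'
#' @param path Hypnogram file path.
#' @param rec The `recording` the stages describe.
#' @return A `hypnogram` with exactly `floor(duration / 30)` epochs.
#' @export
ingest_hypnogram <- function(path, rec) {
  stopifnot(inherits(rec, "recording"))
  hyp <- read_hypnogram(path)
  want <- floor(duration_s(rec) / 30)
  have <- length(unclass(hyp))
  if (abs(have - want) > 1) {
    stop(sprintf("hypnogram (%d epochs) does not align with recording (%d epochs)",
                 have, want), call. = FALSE)
  }
  if (have == want) return(hyp)
  if (have < want) return(hypnogram(c(unclass(hyp), "UNSCORED")))
  warning(sprintf("hypnogram has %d surplus epoch(s); truncated", have - want))
  hypnogram(unclass(hyp)[seq_len(want)])
}

#' Naive rule-based sleep stager
#'
#' A deliberately simple per-epoch stager used to exercise the pipeline
#' end-to-end on synthetic data. It is **not** a re-implementation of any
#' trained sleep-staging classifier and makes no claim to accuracy on real
#' EEG; production use should ingest externally scored hypnograms via
#' [ingest_hypnogram()].
#'
#' Per 30-s epoch, applied in order:
#' 1. relative delta power (of the four canonical bands) > `delta_n3` → `N3`;
#' 2. a sigma-band (12--16 Hz) RMS burst — max sliding RMS over
#'    `burst_ratio` times the epoch's median RMS → `N2`;
#' 3. large EOG deflections (max |bipolar EOG| > `eog_mads` times the
#'    epoch's MAD) with relative delta < `delta_rem` → `REM`;
#' 4. alpha fraction > `alpha_w` → `W`;
#' 5. otherwise `N1`. A silent epoch (zero power) falls back to `W`.
#'
#' @param eeg Staging EEG channel (numeric, µV), ideally 0.1--40 Hz
#'   filtered at 100 Hz.
#' @param eog_bipolar Bipolar EOG (`EOG2 - EOG1`), same length and rate.
#' @param fs Sampling rate, Hz.
#' @param delta_n3,burst_ratio,eog_mads,delta_rem,alpha_w Rule thresholds.
#' @return A `hypnogram` with `floor(length(eeg) / (30 fs))` epochs.
#' @export
naive_stage <- function(eeg, eog_bipolar, fs, delta_n3 = 0.56,
                        burst_ratio = 2.5, eog_mads = 8, delta_rem = 0.55,
                        alpha_w = 0.17) {
  stopifnot(length(eeg) == length(eog_bipolar))
  epl <- round(30 * fs)
  n_ep <- floor(length(eeg) / epl)
  if (n_ep < 1) stop("need at least one full 30-s epoch", call. = FALSE)
  sigma <- bandpass(eeg, 12, 16, fs = fs)
  stages <- character(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * epl + 1):(e * epl)
    seg <- eeg[idx]
    if (stats::sd(seg) < 1e-9) { stages[e] <- "W"; next }
    psd <- welch_raw(seg, fs)
    bands <- default_bands()
    bp <- purrr::map2_dbl(bands$low_hz, bands$high_hz,
                          function(lo, hi) band_power(psd, lo, hi))
    rd <- bp[1] / sum(bp)
    ra <- bp[3] / sum(bp)
    if (rd > delta_n3) { stages[e] <- "N3"; next }
    r <- sliding_rms(sigma[idx], fs, 0.3, 0.1)
    if (length(r$rms) && stats::median(r$rms) > 0 &&
        max(r$rms) > burst_ratio * stats::median(r$rms)) {
      stages[e] <- "N2"; next
    }
    eo <- eog_bipolar[idx]
    mad_eo <- stats::mad(eo)
    if (mad_eo > 0 && max(abs(eo)) > eog_mads * mad_eo && rd < delta_rem) {
      stages[e] <- "REM"; next
    }
    if (ra > alpha_w) { stages[e] <- "W"; next }
    stages[e] <- "N1"
  }
  hypnogram(stages)
}
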