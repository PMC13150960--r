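#' Sleep-stage vocabulary
#'
#' Stage labels follow AASM scoring: wake (`W`), NREM stages `N1`--`N3`,
#' `REM`, plus `UNSCORED` for epochs without a label.
#'
#' @format Character vector of the six valid stage tokens.
#' @export
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM", "UNSCORED")

#' NREM sleep stages
#' @format Character vector of the three NREM stage tokens.
#' @export
NREM_STAGES <- c("N1", "N2", "N3")

#' Sleep stages (everything except wake and unscored)
#' @format Character vector of sleep stage tokens.
#' @export
SLEEP_STAGES <- c("N1", "N2", "N3", "REM")

#' Construct a multi-channel EEG/EOG recording
#'
#' A `recording` is the in-memory form of one night of patch data: a
#' channels-by-time numeric matrix in microvolts, already referenced to the
#' nose electrode, with a sampling rate and ordered channel labels.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns (µV).
#'   A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row. Defaults to `EEG1`, `EEG2`, `EOG1`, `EOG2` for a 4-row matrix.
#' @param start_time Optional `POSIXct` recording start.
#' @param meta Free-form named list of metadata (gap reports, provenance).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      start_time = NULL, meta = list()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(samples) == 4) {
      c("EEG1", "EEG2", "EOG1", "EOG2")
    } else {
      paste0("ch", seq_len(nrow(samples)))
    }
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("one channel label per row of `samples` is required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         start_time = start_time, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param x A `recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "recording"))
  ncol(x$samples) / x$fs
}

#' Extract one channel of a recording as a numeric vector
#' @param x A `recording`.
#' @param channel Channel label or row index.
#' @return Numeric vector of samples (µV).
#' @export
channel <- function(x, channel) {
  stopifnot(inherits(x, "recording"))
  if (is.character(channel) && !channel %in% x$channel_labels) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(x$channel_labels, collapse = ", ")), call. = FALSE)
  }
  as.numeric(x$samples[channel, ])
}

#' Require a recording to carry the standard patch montage
#'
#' Downstream staging and detection assume the four-channel montage
#' `EEG1`, `EEG2`, `EOG1`, `EOG2`.
#'
#' @param x A `recording`.
#' @return `x`, invisibly, if the montage is complete.
#' @export
check_patch_montage <- function(x) {
  stopifnot(inherits(x, "recording"))
  need <- c("EEG1", "EEG2", "EOG1", "EOG2")
  missing <- setdiff(need, x$channel_labels)
  if (length(missing)) {
    stop("recording is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Construct a hypnogram
#'
#' One stage token per 30-second epoch.
#'
#' @param stages Character vector of stage labels
#'   (`W`, `N1`, `N2`, `N3`, `REM`, `UNSCORED`).
#' @param epoch_len Epoch length in seconds; fixed at 30 by AASM convention.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len = 30) {
  stages <- as.character(stages)
  if (length(stages) < 1) stop("a hypnogram needs at least one epoch", call. = FALSE)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (epoch_len != 30) stop("epoch_len must be 30 s", call. = FALSE)
  structure(stages, epoch_len = epoch_len, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %d epochs (%.1f min)\n", length(x), length(x) * 0.5))
  print(tab)
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param x A `hypnogram`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) length(unclass(x))

#' Tidy a hypnogram into an epoch table
#'
#' @param x A `hypnogram`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `onset_s` and `stage` columns.
#' @method tidy hypnogram
#' @export
tidy.hypnogram <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(unclass(x)),
    onset_s = (seq_along(unclass(x)) - 1) * 30,
    stage = factor(unclass(x), levels = STAGE_LEVELS)
  )
}

#' Stage label at an arbitrary time
#' @param hyp A `hypnogram`.
#' @param t_s Time(s) in seconds from recording start.
#' @return Character stage labels (`UNSCORED` beyond the hypnogram's end).
#' @export
stage_at <- function(hyp, t_s) {
  idx <- floor(t_s / 30) + 1
  out <- rep("UNSCORED", length(idx))
  ok <- idx >= 1 & idx <= length(unclass(hyp))
  out[ok] <- unclass(hyp)[idx[ok]]
  out
}
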