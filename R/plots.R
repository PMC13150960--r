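#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hypnogram
#'
#' Step plot of stage against clock time, deepest stage lowest — the
#' standard hypnogram display.
#'
#' @param object A `hypnogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  d <- tidy(object)
  order <- c("N3", "N2", "N1", "REM", "W", "UNSCORED")
  d$stage <- factor(as.character(d$stage), levels = order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$onset_s / 3600, y = .data$stage,
                                  group = 1)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(x = "Time (h)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot a Welch PSD
#'
#' @param object A `psd` from [welch_psd()].
#' @param max_freq_hz Truncate the frequency axis.
#' @param ... Unused.
#' @return A ggplot (log10 power axis).
#' @method autoplot psd
#' @export
autoplot.psd <- function(object, max_freq_hz = 40, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$freq_hz > 0 & d$freq_hz <= max_freq_hz, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD~(mu*V^2/Hz))) +
    ggplot2::theme_minimal()
}

#' Plot a multitaper spectrogram
#'
#' dB-scaled time-frequency raster, the whole-night QC display.
#'
#' @param object A `spectrogram`.
#' @param floor_db Dynamic-range floor relative to the maximum.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrogram
#' @export
autoplot.spectrogram <- function(object, floor_db = -40, ...) {
  db <- 10 * log10(object$power)
  db <- db - max(db, na.rm = TRUE)
  db[db < floor_db] <- floor_db
  d <- tibble::tibble(
    time_s = rep(object$time_s, times = length(object$freq_hz)),
    freq_hz = rep(object$freq_hz, each = length(object$time_s)),
    db = as.vector(db)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s / 3600, y = .data$freq_hz,
                                  fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Time (h)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot group-comparison effect sizes
#'
#' Rank-biserial correlations with their confidence intervals, one row per
#' measure; filled points mark p < .05.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  d <- tidy(object)
  gr <- attr(object, "groups")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_rank_biserial,
                                  y = stats::reorder(.data$measure,
                                                     .data$r_rank_biserial))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "p < .05") +
    ggplot2::labs(
      x = sprintf("Rank-biserial r (positive: %s > %s)", gr[1], gr[2]),
      y = NULL) +
    ggplot2::theme_minimal()
}
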