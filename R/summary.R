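#' Macroarchitecture metrics for one night
#'
#' Total sleep time is 0.5 min per epoch scored `N1`, `N2`, `N3` or `REM`;
#' time in bed is the full recording duration (patch-on to patch-off);
#' sleep efficiency is `100 * TST / TIB`; stage percentages are of TST.
#' With zero sleep epochs the stage percentages are returned `NA` with a
#' warning and efficiency is 0.
#'
#' @param hyp A `hypnogram`.
#' @param recording_duration_min Recording duration (minutes), used as TIB.
#' @param mask Optional `artifact_mask`, carried through to the
#'   artifact-free stage-minute columns used as density denominators.
#' @return One-row tibble: `tst_min`, `tib_min`, `sleep_efficiency`,
#'   `pct_n1`, `pct_n2`, `pct_n3`, `pct_rem`, and artifact-free
#'   `clean_min_n2`, `clean_min_n3`, `clean_min_nrem`.
#' @export
score_night <- function(hyp, recording_duration_min, mask = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(unclass(hyp)) * 0.5 > recording_duration_min + 0.5) {
    stop("hypnogram is longer than the recording", call. = FALSE)
  }
  st <- unclass(hyp)
  n_sleep <- sum(st %in% SLEEP_STAGES)
  tst <- 0.5 * n_sleep
  se <- if (recording_duration_min > 0) 100 * tst / recording_duration_min else 0
  pct <- function(stage) {
    if (n_sleep == 0) return(NA_real_)
    100 * sum(st == stage) / n_sleep
  }
  if (n_sleep == 0) {
    warning("no sleep epochs: stage percentages undefined")
    se <- 0
  }
  tibble::tibble(
    tst_min = tst, tib_min = recording_duration_min, sleep_efficiency = se,
    pct_n1 = pct("N1"), pct_n2 = pct("N2"), pct_n3 = pct("N3"),
    pct_rem = pct("REM"),
    clean_min_n2 = clean_stage_minutes(hyp, mask, "N2"),
    clean_min_n3 = clean_stage_minutes(hyp, mask, "N3"),
    clean_min_nrem = clean_stage_minutes(hyp, mask, NREM_STAGES)
  )
}

#' Average night summaries into a per-participant summary
#'
#' Unweighted arithmetic mean of every numeric metric across usable
#' nights; a metric undefined on some night (`NA`) is skipped for that
#' night, with the number of contributing nights reported per metric in
#' attribute `n_contributing`.
#'
#' @param nights Tibble of night summaries (one row per usable night),
#'   e.g. stacked [score_night()] rows plus density/spectral columns.
#' @param participant_id,group Carried into the output when supplied.
#' @return One-row tibble of means plus `n_usable_nights`.
#' @export
aggregate_participant <- function(nights, participant_id = NA_character_,
                                  group = NA_character_) {
  stopifnot(is.data.frame(nights))
  if (!nrow(nights)) stop("no usable nights to aggregate", call. = FALSE)
  num <- vapply(nights, is.numeric, logical(1))
  means <- lapply(nights[num], function(v) mean(v, na.rm = TRUE))
  means <- lapply(means, function(v) if (is.nan(v)) NA_real_ else v)
  out <- tibble::as_tibble(means)
  out <- dplyr::bind_cols(
    tibble::tibble(participant_id = participant_id, group = group,
                   n_usable_nights = nrow(nights)),
    out)
  attr(out, "n_contributing") <-
    vapply(nights[num], function(v) sum(!is.na(v)), integer(1))
  out
}

pct_str <- function(n, d, digits) {
  if (d == 0) return(sprintf("%d/%d (0)", n, d))
  sprintf("%d/%d (%s)", n, d, formatC(round(100 * n / d, digits),
                                      format = "f", digits = digits))
}

#' Build a data-retention ledger from a cohort manifest
#'
#' Splits participants into Panel A (zero usable nights) and Panel B (at
#' least one usable night) per group and reports the standard retention
#' fractions: in Panel A each loss category over the panel's scheduled
#' nights (percent rounded to the nearest integer); in Panel B usable
#' nights over nights with device use, and each loss category over
#' scheduled nights (one decimal). "Nights with device use" are all
#' scheduled nights except `not_worn`. Also reports, per group, the share
#' of all lost nights attributable to poor reference-electrode adhesion.
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @return A `retention_ledger`: list with `counts` (per group x panel) and
#'   `formatted` (tibble of `group`, `panel`, `label`, `value` strings).
#' @export
build_retention_ledger <- function(manifest) {
  m <- validate_manifest(manifest)
  per_part <- m |>
    dplyr::group_by(.data$group, .data$participant_id) |>
    dplyr::summarise(n_usable = sum(.data$disposition == "usable"),
                     .groups = "drop")
  m <- dplyr::left_join(m, per_part, by = c("group", "participant_id")) |>
    dplyr::mutate(panel = ifelse(.data$n_usable == 0, "A", "B"))
  counts <- m |>
    dplyr::group_by(.data$group, .data$panel) |>
    dplyr::summarise(
      n_participants = dplyr::n_distinct(.data$participant_id),
      scheduled = dplyr::n(),
      device_use = sum(.data$disposition != "not_worn"),
      usable = sum(.data$disposition == "usable"),
      not_worn = sum(.data$disposition == "not_worn"),
      adhesion = sum(.data$disposition == "poor_reference_adhesion"),
      bluetooth = sum(.data$disposition == "bluetooth"),
      .groups = "drop")
  stopifnot(all(counts$usable + counts$not_worn + counts$adhesion +
                  counts$bluetooth == counts$scheduled))
  fmt <- list()
  for (g in unique(counts$group)) {
    a <- counts[counts$group == g & counts$panel == "A", ]
    if (nrow(a)) {
      fmt[[length(fmt) + 1]] <- tibble::tibble(
        group = g, panel = "A",
        label = c("poor_reference_adhesion", "not_worn", "bluetooth"),
        value = c(pct_str(a$adhesion, a$scheduled, 0),
                  pct_str(a$not_worn, a$scheduled, 0),
                  pct_str(a$bluetooth, a$scheduled, 0)))
    }
    b <- counts[counts$group == g & counts$panel == "B", ]
    if (nrow(b)) {
      fmt[[length(fmt) + 1]] <- tibble::tibble(
        group = g, panel = "B",
        label = c("usable_of_device_use", "not_worn_of_scheduled",
                  "poor_reference_adhesion_of_scheduled",
                  "bluetooth_of_scheduled"),
        value = c(pct_str(b$usable, b$device_use, 1),
                  pct_str(b$not_worn, b$scheduled, 1),
                  pct_str(b$adhesion, b$scheduled, 1),
                  pct_str(b$bluetooth, b$scheduled, 1)))
    }
    # share of all lost nights (both panels) due to adhesion
    gc <- counts[counts$group == g, ]
    lost <- sum(gc$scheduled - gc$usable)
    fmt[[length(fmt) + 1]] <- tibble::tibble(
      group = g, panel = "all",
      label = "adhesion_of_lost",
      value = pct_str(sum(gc$adhesion), lost, 0))
  }
  structure(list(counts = counts, formatted = dplyr::bind_rows(fmt)),
            class = "retention_ledger")
}

#' @export
print.retention_ledger <- function(x, ...) {
  cat("Sleep EEG data retention\n")
  for (g in unique(x$formatted$group)) {
    cat(sprintf("\n%s:\n", g))
    sub <- x$formatted[x$formatted$group == g, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  [%s] %-38s %s\n", sub$panel[i], sub$label[i], sub$value[i]))
    }
  }
  invisible(x)
}
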