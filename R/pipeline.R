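#' Pipeline run configuration
#'
#' Bundles every tunable of the per-night pipeline with its default:
#' quality-control band 0.3--35 Hz, 59--61 Hz notch (applied only at the
#' native rate), 100 Hz staging rate, 5-s / |z| > 3 artifact windows,
#' detector parameters of [detector_params()], 4-s / 50% Welch windows,
#' 0.5--45 Hz band for stage-wise PSDs, and the staging source (`"file"`
#' to ingest hypnograms, `"naive"` for the rule-based test stager).
#'
#' @param qc_band QC band-pass edges, Hz.
#' @param notch_band Mains notch edges, Hz (`NULL` disables).
#' @param staging_fs Downsampled rate for staging and detection, Hz.
#' @param artifact_window_s,artifact_z Artifact window and z threshold.
#' @param detector [detector_params()] list.
#' @param welch_window_s,welch_overlap Welch settings.
#' @param psd_band Band-pass applied before stage-wise PSDs, Hz.
#' @param stager `"file"` or `"naive"`.
#' @param snr_channel Channel used for the delta SNR.
#' @param seed Seed recorded in outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(qc_band = c(0.3, 35), notch_band = c(59, 61),
                       staging_fs = 100, artifact_window_s = 5,
                       artifact_z = 3, detector = detector_params(),
                       welch_window_s = 4, welch_overlap = 0.5,
                       psd_band = c(0.5, 45), stager = c("file", "naive"),
                       snr_channel = "EEG1", seed = 1) {
  stager <- match.arg(stager)
  structure(as.list(environment()), class = "run_config")
}

# Concatenate artifact-free epochs of given stage(s) from one channel.
stage_signal <- function(sig, fs, hyp, mask, stages) {
  st <- unclass(hyp)
  idx <- which(st %in% stages)
  if (length(idx)) idx <- idx[epoch_is_clean(mask, idx)]
  if (!length(idx)) return(numeric())
  epl <- round(30 * fs)
  unlist(lapply(idx, function(e) {
    a <- (e - 1) * epl + 1
    b <- min(e * epl, length(sig))
    if (a > length(sig)) numeric() else sig[a:b]
  }))
}

#' Process one night end-to-end
#'
#' Stage order: read → QC filters (band-pass, notch at native rate) →
#' quality gate → downsample to the staging rate → artifact mask → staging
#' (file ingest or naive stager) → event detection and densities →
#' stage-wise Welch band powers, composite NREM delta and SNR → macro
#' summary.
#'
#' @param recording_path EDF (`.edf`) or patch CSV path.
#' @param hypnogram_path Hypnogram path (required when
#'   `config$stager == "file"`).
#' @param config A [run_config()].
#' @param actigraphy_tst_min Optional actigraphy total sleep time, minutes.
#' @return List with `usable` (logical), `reason`, `summary` (one-row
#'   NightSummary tibble or `NULL`), `events` (tibble), `mask`, `hypnogram`.
#' @export
run_night <- function(recording_path, hypnogram_path = NULL,
                      config = run_config(), actigraphy_tst_min = NULL) {
  rec <- if (grepl("\\.edf$", recording_path, ignore.case = TRUE)) {
    read_edf(recording_path)
  } else {
    read_patch_csv(recording_path)
  }
  process_night(rec, hypnogram_path, config, actigraphy_tst_min)
}

#' Process an in-memory recording end-to-end
#'
#' The computational body of [run_night()], for recordings already in
#' memory (e.g. straight from [synthesize_night()]).
#'
#' @param rec A `recording`.
#' @param hyp A `hypnogram`, or a path to one, or `NULL` with
#'   `config$stager == "naive"`.
#' @inheritParams run_night
#' @return As [run_night()].
#' @export
process_night <- function(rec, hyp = NULL, config = run_config(),
                          actigraphy_tst_min = NULL) {
  if (ncol(rec$samples) == 0) {
    return(list(usable = FALSE, reason = "not_worn", summary = NULL,
                events = empty_events(), mask = NULL, hypnogram = NULL))
  }
  check_patch_montage(rec)
  hypnogram_path <- if (is.character(hyp)) hyp else NULL
  if (duration_s(rec) < 60) {
    return(list(usable = FALSE, reason = "bluetooth", summary = NULL,
                events = empty_events(), mask = NULL, hypnogram = NULL))
  }
  rec_f <- bandpass(rec, config$qc_band[1], config$qc_band[2])
  if (!is.null(config$notch_band) && config$notch_band[2] < rec$fs / 2) {
    rec_f <- notch(rec_f, config$notch_band[1], config$notch_band[2])
  }
  gate <- quality_gate(rec_f, actigraphy_tst_min = actigraphy_tst_min)
  if (!gate$keep) {
    # short files are counted with connectivity losses; garbled-but-long
    # files with reference-adhesion losses
    reason <- if (duration_s(rec) / 60 < 300) "bluetooth" else
      "poor_reference_adhesion"
    return(list(usable = FALSE, reason = reason, summary = NULL,
                events = empty_events(), mask = NULL, hypnogram = NULL))
  }
  rec100 <- resample_to(rec_f, config$staging_fs)
  mask <- detect_artifacts(rec100, config$artifact_window_s, config$artifact_z)
  hyp <- if (config$stager == "file") {
    if (inherits(hyp, "hypnogram")) {
      hyp
    } else if (!is.null(hypnogram_path) && nzchar(hypnogram_path)) {
      ingest_hypnogram(hypnogram_path, rec100)
    } else {
      stop("config$stager == 'file' but no hypnogram given", call. = FALSE)
    }
  } else {
    eeg_st <- bandpass(channel(rec100, "EEG1"), 0.1, 40, fs = rec100$fs)
    eog_bi <- channel(rec100, "EOG2") - channel(rec100, "EOG1")
    naive_stage(eeg_st, eog_bi, rec100$fs)
  }
  eeg1 <- channel(rec100, "EEG1")
  fs <- rec100$fs
  so <- detect_slow_oscillations(eeg1, hyp, mask, fs = fs,
                                 params = config$detector)
  sigma <- bandpass(eeg1, config$detector$spindle_band[1],
                    config$detector$spindle_band[2], fs = fs)
  sp2 <- detect_spindles(eeg1, hyp, "N2", mask, fs = fs,
                         params = config$detector, sigma_signal = sigma)
  sp3 <- detect_spindles(eeg1, hyp, "N3", mask, fs = fs,
                         params = config$detector, sigma_signal = sigma)
  macro <- score_night(hyp, duration_s(rec) / 60, mask)
  dens_or_na <- function(ev, minutes, f) {
    if (minutes > 0) f(ev, minutes) else NA_real_
  }
  so_d <- dens_or_na(so, macro$clean_min_nrem, so_density)
  sp2_d <- dens_or_na(sp2, macro$clean_min_n2, spindle_density)
  sp3_d <- dens_or_na(sp3, macro$clean_min_n3, spindle_density)
  # stage-wise relative band power on the 0.5-45 Hz filtered signal
  eeg_psd <- bandpass(eeg1, config$psd_band[1],
                      min(config$psd_band[2], fs / 2 - 1), fs = fs)
  rel_delta <- function(stg) {
    sigc <- stage_signal(eeg_psd, fs, hyp, mask, stg)
    if (length(sigc) < config$welch_window_s * fs) return(NA_real_)
    rel <- relative_band_power(
      welch_psd(sigc, fs, config$welch_window_s, config$welch_overlap))
    rel$rel_power[rel$band == "delta"]
  }
  rd2 <- rel_delta("N2"); rd3 <- rel_delta("N3")
  nrem_delta <- if (!is.na(rd2) || !is.na(rd3)) {
    composite_nrem_delta(ifelse(is.na(rd2), 0, rd2),
                         ifelse(is.na(rd3), 0, rd3),
                         ifelse(is.na(rd2), 0, macro$clean_min_n2),
                         ifelse(is.na(rd3), 0, macro$clean_min_n3))
  } else NA_real_
  snr <- tryCatch(
    compute_snr_db(rec100, hyp, mask, channel = config$snr_channel),
    error = function(e) NA_real_)
  summary <- dplyr::bind_cols(
    macro,
    tibble::tibble(so_density = so_d, spindle_density_n2 = sp2_d,
                   spindle_density_n3 = sp3_d, rel_delta_n2 = rd2,
                   rel_delta_n3 = rd3, nrem_rel_delta = nrem_delta,
                   snr_db = snr))
  list(usable = TRUE, reason = "ok", summary = summary,
       events = dplyr::bind_rows(so, sp2, sp3), mask = mask, hypnogram = hyp)
}

#' Process a whole cohort: nights, participants, ledger, group comparison
#'
#' Runs [run_night()] for every manifest row whose disposition is
#' `usable`, never letting one night's failure abort the cohort (failed
#' nights are logged and re-categorised); averages usable nights per
#' participant; builds the retention ledger from the effective
#' dispositions; and, when both groups retain at least one participant,
#' compares the standard measure set between groups.
#'
#' @param manifest Manifest tibble or path to a manifest CSV.
#' @param config A [run_config()].
#' @param measures Measure columns compared between groups.
#' @param quiet Suppress per-night progress messages.
#' @return List with `nights` (per-night status tibble), `participants`
#'   (per-participant summary tibble), `ledger` (`retention_ledger`) and
#'   `comparison` (`group_comparison` or `NULL`).
#' @export
run_cohort <- function(manifest, config = run_config(),
                       measures = c("tst_min", "sleep_efficiency", "pct_n1",
                                    "pct_n2", "pct_n3", "pct_rem",
                                    "so_density", "nrem_rel_delta",
                                    "spindle_density_n2",
                                    "spindle_density_n3"),
                       quiet = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  night_rows <- list()
  summaries <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    eff <- row$disposition
    summ <- NULL
    if (row$disposition == "usable") {
      res <- tryCatch(
        run_night(row$recording_path, row$hypnogram_path, config,
                  actigraphy_tst_min = row$actigraphy_tst_min),
        error = function(e) {
          if (!quiet) message(sprintf("night %s/%d failed: %s",
                                      row$participant_id, row$night_index,
                                      conditionMessage(e)))
          list(usable = FALSE, reason = "poor_reference_adhesion",
               summary = NULL)
        })
      if (res$usable) {
        summ <- res$summary
      } else {
        eff <- res$reason
      }
    }
    if (!is.null(summ)) {
      summaries[[length(summaries) + 1]] <-
        dplyr::bind_cols(tibble::tibble(participant_id = row$participant_id,
                                        group = row$group,
                                        night_index = row$night_index), summ)
    }
    night_rows[[length(night_rows) + 1]] <- tibble::tibble(
      participant_id = row$participant_id, group = row$group,
      night_index = row$night_index, disposition = eff,
      usable = !is.null(summ))
  }
  nights <- dplyr::bind_rows(night_rows)
  eff_manifest <- manifest
  eff_manifest$disposition <- nights$disposition
  ledger <- build_retention_ledger(eff_manifest)
  participants <- NULL
  comparison <- NULL
  if (length(summaries)) {
    all_nights <- dplyr::bind_rows(summaries)
    participants <- all_nights |>
      dplyr::group_by(.data$participant_id, .data$group) |>
      dplyr::group_modify(function(d, key) {
        aggregate_participant(dplyr::select(d, -"night_index"))[, -(1:2)]
      }) |>
      dplyr::ungroup()
    have <- table(participants$group)
    if (length(have) == 2 && all(have >= 1)) {
      msr <- intersect(measures, names(participants))
      msr <- msr[vapply(msr, function(m) {
        all(tapply(!is.na(participants[[m]]), participants$group, any))
      }, logical(1))]
      if (length(msr)) comparison <- compare_groups(participants, msr)
    } else {
      message("fewer than one usable participant per group; comparison skipped")
    }
  }
  list(nights = nights, participants = participants, ledger = ledger,
       comparison = comparison)
}
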