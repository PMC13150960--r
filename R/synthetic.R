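#' Per-stage synthesis parameters
#'
#' One row per sleep stage describing what the generator renders during
#' epochs of that stage: the RMS of the 1/f background, slow-oscillation
#' and spindle injection rates and amplitudes, the spindle carrier band,
#' waking alpha amplitude, and the REM eye-movement rate.
#'
#' @param stage Stage label.
#' @param background_amp Background 1/f RMS, µV.
#' @param so_rate Slow oscillations per minute.
#' @param so_amp SO peak-to-peak amplitude, µV (jittered ±20% per event).
#' @param spindle_rate Spindles per minute.
#' @param spindle_amp Spindle envelope peak, µV.
#' @param spindle_freq_low,spindle_freq_high Carrier band, Hz (within 12--16).
#' @param alpha_amp Waking alpha (10 Hz) amplitude, µV.
#' @param rem_eog_rate Large opposite-polarity EOG deflections per minute.
#' @return One-row tibble.
#' @export
stage_params <- function(stage, background_amp = 15, so_rate = 0, so_amp = 0,
                         spindle_rate = 0, spindle_amp = 0,
                         spindle_freq_low = 12, spindle_freq_high = 16,
                         alpha_amp = 0, rem_eog_rate = 0) {
  stopifnot(stage %in% STAGE_LEVELS,
            background_amp >= 0, so_rate >= 0, so_amp >= 0,
            spindle_rate >= 0, spindle_amp >= 0,
            spindle_freq_low >= 12, spindle_freq_high <= 16,
            spindle_freq_low < spindle_freq_high,
            alpha_amp >= 0, rem_eog_rate >= 0)
  tibble::tibble(stage = stage, background_amp = background_amp,
                 so_rate = so_rate, so_amp = so_amp,
                 spindle_rate = spindle_rate, spindle_amp = spindle_amp,
                 spindle_freq_low = spindle_freq_low,
                 spindle_freq_high = spindle_freq_high,
                 alpha_amp = alpha_amp, rem_eog_rate = rem_eog_rate)
}

#' Default per-stage parameters for a study group
#'
#' The young defaults place ~3 spindles/min in N2 and deep-sleep slow
#' oscillations in N3; the old defaults cut the spindle rate to a third,
#' mirroring the roughly 3:1 young:old spindle-density ratio reported for
#' forehead EEG in aging cohorts. Stage-dwell differences (old N3 about
#' half of young) live in [hypnogram_params()], not here.
#'
#' @param group `"young"` or `"old"`.
#' @return Tibble with one row per stage.
#' @export
default_stage_params <- function(group = c("young", "old")) {
  group <- match.arg(group)
  spindle_rate_n2 <- if (group == "young") 3 else 1
  spindle_rate_n3 <- if (group == "young") 0.3 else 0.1
  dplyr::bind_rows(
    stage_params("W", background_amp = 15, alpha_amp = 10),
    stage_params("N1", background_amp = 15),
    stage_params("N2", background_amp = 20, spindle_rate = spindle_rate_n2,
                 spindle_amp = 15, spindle_freq_low = 12.5,
                 spindle_freq_high = 15.5),
    stage_params("N3", background_amp = 30, so_rate = 8, so_amp = 150,
                 spindle_rate = spindle_rate_n3, spindle_amp = 12,
                 spindle_freq_low = 12.5, spindle_freq_high = 15.5),
    stage_params("REM", background_amp = 15, rem_eog_rate = 10),
    stage_params("UNSCORED", background_amp = 10)
  )
}

#' Hypnogram-generator parameters
#'
#' A semi-Markov night model: an initial wake run, then repeating
#' NREM--REM cycles (N1, descending N2, N3, ascending N2, REM), with N3
#' dwell decaying and REM growing across cycles as in real nights, and
#' brief awakenings between cycles. Dwells are Poisson draws (minimum 1
#' epoch) around the stated means, in 30-s epochs.
#'
#' @param wake_start_mean Mean initial wake run (epochs).
#' @param n1,n2_desc,n3,n2_asc,rem Mean dwell per cycle segment (epochs).
#' @param n3_decay Multiplier on the N3 dwell per successive cycle.
#' @param rem_growth Multiplier on the REM dwell per successive cycle.
#' @param wake_between_mean Mean brief-awakening run between cycles (epochs).
#' @param n3_dwell_factor Global scale on N3 dwell; epochs trimmed from N3
#'   are returned to ascending N2 (the old-group default is 0.5).
#' @return Named list of parameters.
#' @export
hypnogram_params <- function(wake_start_mean = 14, n1 = 6, n2_desc = 60,
                             n3 = 60, n2_asc = 48, rem = 37,
                             n3_decay = 0.7, rem_growth = 1.05,
                             wake_between_mean = 2, n3_dwell_factor = 1) {
  as.list(environment())
}

#' Hypnogram parameters for a study group
#' @param group `"young"` or `"old"`.
#' @return As [hypnogram_params()]; old halves the N3 dwell.
#' @export
default_hypnogram_params <- function(group = c("young", "old")) {
  group <- match.arg(group)
  hypnogram_params(n3_dwell_factor = if (group == "young") 1 else 0.5)
}

#' Generate a synthetic hypnogram
#'
#' @param params See [hypnogram_params()].
#' @param total_epochs Number of 30-s epochs (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `hypnogram` of exactly `total_epochs` epochs, starting with at
#'   least one `W` epoch.
#' @export
generate_hypnogram <- function(params = hypnogram_params(), total_epochs,
                               seed = 1) {
  if (!is.numeric(total_epochs) || total_epochs < 1) {
    stop("total_epochs must be a positive count", call. = FALSE)
  }
  total_epochs <- as.integer(total_epochs)
  set.seed(seed)
  dwell <- function(mean) max(1L, stats::rpois(1, mean))
  stages <- rep("W", dwell(params$wake_start_mean))
  cyc <- 0
  while (length(stages) < total_epochs) {
    cyc <- cyc + 1
    n3_mean <- params$n3 * params$n3_dwell_factor * params$n3_decay^(cyc - 1)
    n3_n <- if (n3_mean < 0.5) 0L else dwell(n3_mean)
    # epochs trimmed off N3 are spent in ascending N2 instead
    n2_asc_mean <- params$n2_asc +
      params$n3 * params$n3_decay^(cyc - 1) - n3_mean
    seg <- c(
      rep("N1", dwell(params$n1)),
      rep("N2", dwell(params$n2_desc)),
      rep("N3", n3_n),
      rep("N2", dwell(n2_asc_mean)),
      rep("REM", dwell(params$rem * params$rem_growth^(cyc - 1)))
    )
    wb <- stats::rpois(1, params$wake_between_mean)
    stages <- c(stages, seg, rep("W", wb))
  }
  hypnogram(stages[seq_len(total_epochs)])
}

# Two independent unit-RMS 1/f (power ~ 1/f) Gaussian noise series,
# synthesized in the frequency domain with one complex FFT (the real and
# imaginary parts of the inverse transform of a spectrum with independent
# Gaussian coefficients at every bin are independent). Spectrum flattens
# below f_floor to keep variance finite.
one_over_f_pair <- function(n, fs, f_floor = 0.1) {
  k <- seq_len(n) - 1
  freqs <- pmin(k, n - k) * fs / n          # FFT bin frequencies, folded
  amp <- 1 / sqrt(pmax(freqs, f_floor))
  amp[1] <- 0
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * amp
  z <- stats::fft(spec, inverse = TRUE) / n
  list(Re(z) / stats::sd(Re(z)), Im(z) / stats::sd(Im(z)))
}

# Place `k` event onsets of the given durations in [0, 30) s of one epoch,
# keeping >= 1 s between events; rejection sampling, events that cannot be
# placed are dropped.
place_events <- function(k, durations, epoch_len = 30) {
  if (k == 0) return(numeric())
  out <- rep(NA_real_, k)
  occ_on <- numeric(); occ_end <- numeric()
  for (i in seq_len(k)) {
    d <- durations[i]
    for (try in 1:20) {
      on <- stats::runif(1, 0, epoch_len - d)
      if (!length(occ_on) ||
          all(on >= occ_end + 1 | on + d <= occ_on - 1)) {
        out[i] <- on
        occ_on <- c(occ_on, on); occ_end <- c(occ_end, on + d)
        break
      }
    }
  }
  out
}

# Tukey (tapered cosine) window, alpha = taper fraction.
tukey_window <- function(n, alpha = 0.5) {
  t_ <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t_ < alpha / 2
  hi <- t_ > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t_[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t_[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Synthesize one night of patch EEG/EOG from a hypnogram
#'
#' Renders a 4-channel recording (`EEG1`, `EEG2`, `EOG1`, `EOG2`): per-stage
#' scaled 1/f background on every channel, plus injected stage-specific
#' events, all logged to a ground-truth object:
#'
#' * N3 (and any stage with `so_rate > 0`): biphasic slow oscillations —
#'   one period of a 0.75-Hz sine starting on the down phase (1.33 s),
#'   peak-to-peak amplitude jittered ±20%;
#' * N2/N3: spindle bursts — a sinusoid drawn from the stage's carrier band
#'   under a Tukey envelope, duration uniform in 0.5--1.5 s;
#' * REM: large opposite-polarity deflections on the two EOG channels;
#' * W: 10-Hz alpha, plus movement bursts (broadband noise) at
#'   `movement_rate_w` per minute, logged as artifact spans.
#'
#' Events never overlap within an epoch (1-s minimum gap). All random
#' draws are made regardless of amplitude, so setting an amplitude to zero
#' yields, under the same seed, a recording identical to one with events —
#' minus the events.
#'
#' @param hyp A `hypnogram`.
#' @param params Per-stage parameter tibble, see [default_stage_params()].
#' @param fs Sampling rate, Hz (>= 100; the deployed patch records at 250).
#' @param seed Integer seed.
#' @param movement_rate_w Movement bursts per minute of wake.
#' @param movement_amp Movement-burst noise SD, µV (0 disables).
#' @return List with `recording` and `ground_truth` (list of
#'   `true_hypnogram`, `so_events`, `spindle_events`, `artifact_spans`,
#'   `disposition`).
#' @export
synthesize_night <- function(hyp, params = default_stage_params("young"),
                             fs = 250, seed = 1, movement_rate_w = 0.2,
                             movement_amp = 300) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  stages <- unclass(hyp)
  bad <- setdiff(unique(stages), params$stage)
  if (length(bad)) {
    stop("no stage parameters for label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n_ep <- length(stages)
  epl <- 30 * fs
  n <- n_ep * epl
  chans <- c("EEG1", "EEG2", "EOG1", "EOG2")
  sig <- matrix(0, nrow = 4, ncol = n, dimnames = list(chans, NULL))
  p12 <- one_over_f_pair(n, fs)
  p34 <- one_over_f_pair(n, fs)
  sig[1, ] <- p12[[1]]; sig[2, ] <- p12[[2]]
  sig[3, ] <- p34[[1]]; sig[4, ] <- p34[[2]]
  # stage-scaled background RMS; params keyed by stage for fast lookup
  plist <- split(as.data.frame(params), params$stage)
  bg_by_epoch <- vapply(stages, function(s) plist[[s]]$background_amp,
                        numeric(1))
  scale_vec <- rep(bg_by_epoch, each = epl)
  sig <- sweep(sig, 2, scale_vec, "*")
  so_log <- list(); sp_log <- list(); art_log <- list()
  t_ep <- seq(0, 30, length.out = epl + 1)[-(epl + 1)]
  so_dur <- 1 / 0.75
  for (e in seq_len(n_ep)) {
    p <- plist[[stages[e]]]
    off <- (e - 1) * 30
    i0 <- (e - 1) * epl
    add_wave <- function(ch_idx, onset, wave, gain = 1) {
      a <- i0 + round(onset * fs) + 1
      b <- min(a + length(wave) - 1, n)
      for (ci in ch_idx) {
        sig[ci, a:b] <<- sig[ci, a:b] + gain * wave[seq_len(b - a + 1)]
      }
    }
    # slow oscillations
    k_so <- stats::rpois(1, p$so_rate * 0.5)
    if (k_so > 0) {
      ons <- place_events(k_so, rep(so_dur, k_so))
      amps <- p$so_amp * stats::runif(k_so, 0.8, 1.2)
      for (j in seq_len(k_so)) {
        if (is.na(ons[j])) next
        tt <- seq(0, so_dur, by = 1 / fs)
        wave <- -(amps[j] / 2) * sin(2 * pi * 0.75 * tt)
        add_wave(1:2, ons[j], wave, gain = c(1, 0.9)[1])
        if (p$so_amp > 0) {
          so_log[[length(so_log) + 1]] <-
            c(off + ons[j], so_dur, amps[j], e)
        }
      }
    }
    # spindles
    k_sp <- stats::rpois(1, p$spindle_rate * 0.5)
    if (k_sp > 0) {
      durs <- stats::runif(k_sp, 0.5, 1.5)
      ons <- place_events(k_sp, durs)
      freqs <- stats::runif(k_sp, p$spindle_freq_low, p$spindle_freq_high)
      phases <- stats::runif(k_sp, 0, 2 * pi)
      for (j in seq_len(k_sp)) {
        if (is.na(ons[j])) next
        m <- round(durs[j] * fs)
        tt <- seq_len(m) / fs
        wave <- p$spindle_amp * tukey_window(m) *
          sin(2 * pi * freqs[j] * tt + phases[j])
        add_wave(1:2, ons[j], wave)
        if (p$spindle_amp > 0) {
          sp_log[[length(sp_log) + 1]] <-
            c(off + ons[j], durs[j], e, freqs[j])
        }
      }
    }
    # REM eye movements: opposite polarity on the two EOG channels
    k_eog <- stats::rpois(1, p$rem_eog_rate * 0.5)
    if (k_eog > 0) {
      ons <- place_events(k_eog, rep(0.6, k_eog))
      for (j in seq_len(k_eog)) {
        if (is.na(ons[j])) next
        m <- round(0.6 * fs)
        wave <- 100 * sin(pi * seq_len(m) / m)
        add_wave(3, ons[j], wave)
        add_wave(4, ons[j], -wave)
      }
    }
    # waking alpha
    if (p$alpha_amp > 0 || stages[e] == "W") {
      ph <- stats::runif(1, 0, 2 * pi)
      alpha <- p$alpha_amp * sin(2 * pi * 10 * t_ep + ph)
      add_wave(1:2, 0, alpha)
    }
    # movement bursts during wake
    if (stages[e] == "W") {
      k_mv <- stats::rpois(1, movement_rate_w * 0.5)
      if (k_mv > 0) {
        ons <- place_events(k_mv, rep(2, k_mv))
        for (j in seq_len(k_mv)) {
          if (is.na(ons[j])) next
          m <- round(2 * fs)
          burst <- movement_amp * stats::rnorm(m)
          add_wave(1:4, ons[j], burst)
          if (movement_amp > 0) {
            art_log[[length(art_log) + 1]] <- c(off + ons[j], 2)
          }
        }
      }
    }
  }
  so_m <- do.call(rbind, so_log)
  sp_m <- do.call(rbind, sp_log)
  art_m <- do.call(rbind, art_log)
  gt <- list(
    true_hypnogram = hyp,
    so_events = tibble::tibble(
      onset_s = if (length(so_log)) so_m[, 1] else numeric(),
      duration_s = if (length(so_log)) so_m[, 2] else numeric(),
      amplitude_uv = if (length(so_log)) so_m[, 3] else numeric(),
      stage = if (length(so_log)) stages[so_m[, 4]] else character()),
    spindle_events = tibble::tibble(
      onset_s = if (length(sp_log)) sp_m[, 1] else numeric(),
      duration_s = if (length(sp_log)) sp_m[, 2] else numeric(),
      stage = if (length(sp_log)) stages[sp_m[, 3]] else character(),
      freq_hz = if (length(sp_log)) sp_m[, 4] else numeric()),
    artifact_spans = tibble::tibble(
      onset_s = if (length(art_log)) art_m[, 1] else numeric(),
      duration_s = if (length(art_log)) art_m[, 2] else numeric(),
      kind = if (length(art_log)) rep("movement", nrow(art_m)) else character()),
    disposition = "usable"
  )
  list(recording = recording(sig, fs, channel_labels = chans),
       ground_truth = gt)
}

#' Degrade a recording according to a data-loss disposition
#'
#' * `usable`: returned unchanged.
#' * `not_worn`: empty recording (no samples).
#' * `bluetooth`: truncated at a uniform 10--60% of its duration (whole
#'   seconds), emulating a dropped connection.
#' * `poor_reference_adhesion`: from a random point in the first quarter
#'   of the night onward, 5-s windows are flatlined or replaced by
#'   high-amplitude broadband noise, leaving under 5 hours of clean
#'   signal, as when the nose reference electrode detaches.
#'
#' @param rec A `recording`.
#' @param disposition One of the four categories.
#' @param seed Integer seed.
#' @return A degraded `recording`.
#' @export
emulate_data_loss <- function(rec, disposition, seed = 1) {
  stopifnot(inherits(rec, "recording"))
  if (!disposition %in% DISPOSITIONS) {
    stop("unknown disposition: ", disposition, call. = FALSE)
  }
  if (disposition == "usable") return(rec)
  set.seed(seed)
  if (disposition == "not_worn") {
    return(recording(matrix(numeric(0), nrow = nrow(rec$samples), ncol = 0),
                     rec$fs, channel_labels = rec$channel_labels,
                     meta = list(disposition = "not_worn")))
  }
  if (disposition == "bluetooth") {
    frac <- stats::runif(1, 0.1, 0.6)
    keep_s <- max(1, floor(duration_s(rec) * frac))
    out <- rec
    out$samples <- rec$samples[, seq_len(keep_s * rec$fs), drop = FALSE]
    out$meta$disposition <- "bluetooth"
    return(out)
  }
  # poor_reference_adhesion
  out <- rec
  wlen <- round(5 * rec$fs)
  n_win <- floor(ncol(rec$samples) / wlen)
  start_win <- sample.int(max(1, floor(n_win / 4)), 1)
  for (w in start_win:n_win) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    if (stats::runif(1) < 0.7) {
      out$samples[, idx] <- 0                               # flatline
    } else {
      out$samples[, idx] <- matrix(500 * stats::rnorm(length(idx) * 4),
                                   nrow = 4)                # broadband noise
    }
  }
  out$meta$disposition <- "poor_reference_adhesion"
  out
}

#' Specify a synthetic two-group cohort
#'
#' @param n_per_group Participants per group (>= 1).
#' @param nights_per_participant Nights each participant is scheduled for
#'   (default 7).
#' @param total_epochs Epochs per night (default 960 = 8 h).
#' @param fs Sampling rate, Hz.
#' @param loss_probs Named probabilities for `not_worn`,
#'   `poor_reference_adhesion` and `bluetooth`; the remainder is `usable`.
#' @param group_stage_params Named list `young`/`old` of per-stage tables.
#' @param group_hyp_params Named list `young`/`old` of hypnogram parameters.
#' @param movement_rate_w Movement bursts per wake minute.
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 12, nights_per_participant = 7,
                        total_epochs = 960, fs = 250,
                        loss_probs = c(not_worn = 0,
                                       poor_reference_adhesion = 0,
                                       bluetooth = 0),
                        group_stage_params = list(
                          young = default_stage_params("young"),
                          old = default_stage_params("old")),
                        group_hyp_params = list(
                          young = default_hypnogram_params("young"),
                          old = default_hypnogram_params("old")),
                        movement_rate_w = 0.2, seed = 1) {
  stopifnot(n_per_group >= 1, nights_per_participant >= 1)
  bad <- setdiff(names(loss_probs),
                 c("not_worn", "poor_reference_adhesion", "bluetooth"))
  if (length(bad)) stop("unknown loss categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(loss_probs < 0) || sum(loss_probs) > 1) {
    stop("loss probabilities must be in [0,1] and sum to <= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per scheduled night, an EDF recording (after applying the drawn
#' data-loss disposition), the true hypnogram as plain text, and
#' ground-truth event CSVs; plus a cohort manifest CSV. `not_worn` nights
#' produce no files. Fully deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (also written to `manifest.csv`), with the
#'   per-night generation seeds in column `night_seed`.
#' @export
make_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  set.seed(spec$seed)
  groups <- c("young", "old")
  rows <- list()
  p_loss <- c(spec$loss_probs["not_worn"],
              spec$loss_probs["poor_reference_adhesion"],
              spec$loss_probs["bluetooth"])
  p_loss[is.na(p_loss)] <- 0
  probs <- c(usable = 1 - sum(p_loss), not_worn = unname(p_loss[1]),
             poor_reference_adhesion = unname(p_loss[2]),
             bluetooth = unname(p_loss[3]))
  for (g in groups) {
    for (i in seq_len(spec$n_per_group)) {
      pid <- sprintf("%s%02d", toupper(substr(g, 1, 1)), i)
      for (night in seq_len(spec$nights_per_participant)) {
        disp <- sample(names(probs), 1, prob = probs)
        night_seed <- sample.int(.Machine$integer.max - 1, 1)
        rec_path <- ""
        hyp_path <- ""
        acti <- NA_real_
        if (disp != "not_worn") {
          sim <- with_night_seed(spec, g, night_seed)
          rec <- emulate_data_loss(sim$recording, disp, seed = night_seed)
          base <- sprintf("%s_n%d", pid, night)
          rec_path <- file.path(dir, paste0(base, ".edf"))
          hyp_path <- file.path(dir, paste0(base, ".hyp"))
          write_edf(rec, rec_path)
          write_hypnogram(sim$ground_truth$true_hypnogram, hyp_path)
          readr::write_csv(sim$ground_truth$so_events,
                           file.path(dir, paste0(base, "_so.csv")),
                           progress = FALSE)
          readr::write_csv(sim$ground_truth$spindle_events,
                           file.path(dir, paste0(base, "_spindles.csv")),
                           progress = FALSE)
          # the accelerometer watch is worn every night: record its TST
          true_st <- unclass(sim$ground_truth$true_hypnogram)
          acti <- 0.5 * sum(true_st %in% SLEEP_STAGES)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = pid, group = g, night_index = night,
          recording_path = rec_path, hypnogram_path = hyp_path,
          disposition = disp, actigraphy_tst_min = acti,
          night_seed = night_seed)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  manifest
}

#' Write or read a cohort specification as a YAML config file
#'
#' The scalar fields and loss probabilities are serialized; group
#' parameters are written as per-stage tables. Round trip restores an
#' equivalent [cohort_spec()].
#'
#' @param spec A `cohort_spec`.
#' @param path Output (input) YAML path.
#' @return `path` invisibly; `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- list(
    n_per_group = spec$n_per_group,
    nights_per_participant = spec$nights_per_participant,
    total_epochs = spec$total_epochs,
    fs = spec$fs,
    movement_rate_w = spec$movement_rate_w,
    seed = spec$seed,
    loss_probs = as.list(spec$loss_probs),
    group_stage_params = lapply(spec$group_stage_params, function(d) {
      lapply(split(as.data.frame(d), seq_len(nrow(d))), as.list)
    }),
    group_hyp_params = spec$group_hyp_params
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  gsp <- lapply(obj$group_stage_params, function(g) {
    dplyr::bind_rows(lapply(g, tibble::as_tibble))
  })
  cohort_spec(
    n_per_group = obj$n_per_group,
    nights_per_participant = obj$nights_per_participant,
    total_epochs = obj$total_epochs,
    fs = obj$fs,
    loss_probs = unlist(obj$loss_probs),
    group_stage_params = gsp,
    group_hyp_params = obj$group_hyp_params,
    movement_rate_w = obj$movement_rate_w,
    seed = obj$seed
  )
}

# One night's synthesis under a derived seed (hypnogram then signal).
with_night_seed <- function(spec, group, night_seed) {
  hyp <- generate_hypnogram(spec$group_hyp_params[[group]],
                            spec$total_epochs, seed = night_seed)
  synthesize_night(hyp, spec$group_stage_params[[group]], fs = spec$fs,
                   seed = night_seed + 1,
                   movement_rate_w = spec$movement_rate_w)
}
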