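# Shared fixture builders; everything is generated in code at test time.

# A 4-channel white-noise recording of `secs` seconds.
noise_recording <- function(secs, fs = 100, sd = 20, seed = 1) {
  set.seed(seed)
  recording(matrix(stats::rnorm(4 * secs * fs, sd = sd), nrow = 4), fs)
}

# Single-channel sine of given frequency/amplitude/duration.
sine_wave <- function(freq, secs, fs = 100, amp = 1) {
  amp * sin(2 * pi * freq * seq(1 / fs, secs, by = 1 / fs))
}

# Manifest reproducing the study's retention counts: per group, panel A
# participants (zero usable nights) and panel B participants (>= 1 usable),
# with per-category night counts. Dispositions are dealt so that every
# panel-B participant gets at least one usable night.
retention_manifest <- function() {
  mk_panel <- function(group, prefix, n_part, nights, usable, not_worn,
                       adhesion, bluetooth, panel_b) {
    stopifnot(usable + not_worn + adhesion + bluetooth == n_part * nights)
    disp <- character(0)
    if (panel_b) {
      # one usable night per participant first, then the rest round-robin
      disp <- rep("usable", n_part)
      pool <- c(rep("usable", usable - n_part), rep("not_worn", not_worn),
                rep("poor_reference_adhesion", adhesion),
                rep("bluetooth", bluetooth))
    } else {
      pool <- c(rep("not_worn", not_worn),
                rep("poor_reference_adhesion", adhesion),
                rep("bluetooth", bluetooth))
    }
    disp <- c(disp, pool)
    tibble::tibble(
      participant_id = paste0(prefix, rep(seq_len(n_part), times = nights)),
      group = group,
      night_index = rep(seq_len(nights), each = n_part),
      recording_path = "", hypnogram_path = "",
      disposition = disp
    )
  }
  dplyr::bind_rows(
    # young: panel A 7 x 7 = 49 (38 adhesion, 11 not worn)
    mk_panel("young", "YA", 7, 7, 0, 11, 38, 0, panel_b = FALSE),
    # young: panel B 11 x 7 = 77 (25 usable, 14 not worn, 37 adhesion, 1 bt)
    mk_panel("young", "YB", 11, 7, 25, 14, 37, 1, panel_b = TRUE),
    # old: panel A 6 x 7 = 42 (26 adhesion, 16 not worn)
    mk_panel("old", "OA", 6, 7, 0, 16, 26, 0, panel_b = FALSE),
    # old: panel B 12 x 7 = 84 (38 usable, 14 not worn, 31 adhesion, 1 bt)
    mk_panel("old", "OB", 12, 7, 38, 14, 31, 1, panel_b = TRUE)
  )
}

ledger_value <- function(ledger, grp, lbl) {
  f <- ledger$formatted
  f$value[f$group == grp & f$label == lbl]
}
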