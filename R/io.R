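#' @importFrom rlang .data
NULL

DISPOSITIONS <- c("usable", "not_worn", "poor_reference_adhesion", "bluetooth")

# Internal channel name <-> EDF label mapping (patch montage).
edf_label_of <- function(x) {
  map <- c(EEG1 = "EEG Ch1", EEG2 = "EEG Ch2", EOG1 = "EOG Ch1", EOG2 = "EOG Ch2")
  ifelse(x %in% names(map), map[x], x)
}
internal_label_of <- function(x) {
  map <- c("EEG Ch1" = "EEG1", "EEG Ch2" = "EEG2",
           "EOG Ch1" = "EOG1", "EOG Ch2" = "EOG2")
  ifelse(x %in% names(map), map[x], x)
}

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to EDF
#'
#' European Data Format, the interchange standard for sleep EEG: a 256-byte
#' fixed header, one 256-byte header block per signal, and 16-bit
#' little-endian data records. Records are 1 s long, so the recording must
#' contain a whole number of seconds. Physical ranges are set symmetric per
#' channel, so the round-trip quantization error is at most
#' `physical_range / 2^15` per sample. The standard patch channel names are
#' written as `EEG Ch1`, `EEG Ch2`, `EOG Ch1`, `EOG Ch2`.
#'
#' @param x A `recording` with integer `fs` and whole-second duration.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "recording"))
  fs <- x$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate", call. = FALSE)
  n <- ncol(x$samples)
  if (n %% fs != 0) {
    stop("EDF export requires a whole number of seconds of data", call. = FALSE)
  }
  n_rec <- n / fs
  ns <- nrow(x$samples)
  pmax_ <- apply(abs(x$samples), 1, max)
  pmax_ <- pmax(ceiling(pmax_), 1)
  start <- if (inherits(x$start_time, "POSIXct")) x$start_time else
    as.POSIXct("2000-01-01 22:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X X X X", 80)                                  # patient id (anonymous)
  put("Startdate X X X X", 80)
  put(format(start, "%d.%m.%y"), 8)
  put(format(start, "%H.%M.%S"), 8)
  put(256 * (1 + ns), 8)
  put("", 44)
  put(n_rec, 8)
  put(1, 8)                                           # record duration (s)
  put(ns, 4)
  for (lab in edf_label_of(x$channel_labels)) put(lab, 16)
  for (i in seq_len(ns)) put("dry electrode", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(-pmax_[i], 8)
  for (i in seq_len(ns)) put(pmax_[i], 8)
  for (i in seq_len(ns)) put(-32768, 8)
  for (i in seq_len(ns)) put(32767, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(fs, 8)
  for (i in seq_len(ns)) put("", 32)
  # same affine map the reader inverts: [-pmax, pmax] -> [-32768, 32767]
  dig <- round(sweep(x$samples + rep(pmax_, ncol(x$samples)), 1,
                     2 * pmax_ / 65535, "/") - 32768)
  dig[dig > 32767] <- 32767; dig[dig < -32768] <- -32768
  # file layout: per record, each signal's fs samples in turn
  arr <- array(t(dig), dim = c(fs, n_rec, ns))     # sample, record, signal
  writeBin(as.integer(aperm(arr, c(1, 3, 2))), con, size = 2,
           endian = "little")
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the fixed and per-signal headers and the 16-bit data records,
#' rescaling to physical units. All signals must share one sampling rate
#' (the patch writes homogeneous files). Known patch labels are mapped back
#' to the internal `EEG1`/`EEG2`/`EOG1`/`EOG2` names.
#'
#' @param path EDF file path.
#' @return A `recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 256) stop("malformed EDF (byte 0): file shorter than fixed header", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  num <- function(w, at) {
    s <- get(w)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("malformed EDF (byte %d): expected number, got '%s'", at, s),
                       call. = FALSE)
    v
  }
  get(8)                       # version
  get(80); get(80)             # patient / recording id
  date_s <- get(8); time_s <- get(8)
  header_bytes <- num(8, 184)
  get(44)
  n_rec <- num(8, 236)
  rec_dur <- num(8, 244)
  ns <- num(4, 252)
  if (ns < 1 || sz < 256 + ns * 256) {
    stop("malformed EDF (byte 252): signal headers exceed file size", call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) get(16), character(1))
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)                       # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) num(8, 256 + ns * 104), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) num(8, 256 + ns * 112), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) num(8, 256 + ns * 120), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) num(8, 256 + ns * 128), numeric(1))
  for (i in seq_len(ns)) get(80)                      # prefilter
  spr <- vapply(seq_len(ns), function(i) num(8, 256 + ns * 216), numeric(1))
  for (i in seq_len(ns)) get(32)
  if (header_bytes != 256 * (1 + ns)) {
    stop("malformed EDF (byte 184): header size disagrees with signal count",
         call. = FALSE)
  }
  if (length(unique(spr)) != 1) {
    stop("EDF with heterogeneous per-signal rates is not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  n_tot <- n_rec * spr[1] * ns
  d <- readBin(con, integer(), n = n_tot, size = 2, endian = "little",
               signed = TRUE)
  if (length(d) < n_tot) {
    stop(sprintf("malformed EDF (byte %d): truncated data records",
                 256 * (1 + ns) + 2 * length(d)), call. = FALSE)
  }
  arr <- array(d, dim = c(spr[1], ns, n_rec))      # sample, signal, record
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (i in seq_len(ns)) {
    samples[i, ] <- (as.vector(arr[, i, ]) - dmin_[i]) *
      (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
  }
  start <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  recording(samples, fs, channel_labels = internal_label_of(labels),
            start_time = start)
}

#' Read the patch app's CSV dialect
#'
#' The tablet app stores each night as one or more rotation files sharing a
#' prefix (`<prefix>_001.csv`, `<prefix>_002.csv`, ...). Each file holds
#' optional `# key=value` header lines (notably `# fs=250`), then a header
#' row `sample_index,<channel>,...` and one row per sample in µV. Rotation
#' segments are concatenated in file order; any jump in `sample_index`
#' across or within files is recorded as a gap in `meta$gaps` and the
#' missing samples are filled with `NA` (never interpolated).
#'
#' @param path A single CSV file, a vector of rotation files, or a prefix
#'   to be globbed as `<prefix>*.csv`.
#' @param default_fs Sampling rate used when no `# fs=` header is present.
#' @return A `recording` (possibly with `NA` gap samples and a `meta$gaps`
#'   tibble of `onset_s`/`duration_s`).
#' @export
read_patch_csv <- function(path, default_fs = 250) {
  files <- path
  if (length(files) == 1 && !file.exists(files)) {
    files <- sort(Sys.glob(paste0(path, "*.csv")))
  }
  if (!length(files) || !all(file.exists(files))) {
    stop("no patch CSV files found for: ", paste(path, collapse = ", "),
         call. = FALSE)
  }
  fs <- default_fs
  pieces <- lapply(files, function(f) {
    lines <- readLines(f, n = 20)
    if (!length(lines)) stop("empty patch CSV: ", f, call. = FALSE)
    hdr <- grep("^#", lines, value = TRUE)
    m <- regmatches(hdr, regexec("fs\\s*=\\s*([0-9.]+)", hdr))
    for (mm in m) if (length(mm) == 2) fs <<- as.numeric(mm[2])
    readr::read_csv(f, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  })
  dat <- dplyr::bind_rows(pieces)
  if (!nrow(dat)) stop("patch CSV contains no samples", call. = FALSE)
  if (!"sample_index" %in% names(dat)) {
    stop("patch CSV lacks a sample_index column", call. = FALSE)
  }
  idx <- dat$sample_index
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("non-monotonic sample_index across rotation files", call. = FALSE)
  }
  chans <- setdiff(names(dat), "sample_index")
  full <- seq(idx[1], idx[length(idx)])
  gaps <- tibble::tibble(onset_s = numeric(), duration_s = numeric())
  if (length(full) != length(idx)) {
    pos <- match(idx, full)
    mat <- matrix(NA_real_, nrow = length(chans), ncol = length(full))
    for (i in seq_along(chans)) mat[i, pos] <- dat[[chans[i]]]
    d <- diff(idx)
    at <- which(d > 1)
    gaps <- tibble::tibble(
      onset_s = (idx[at] - idx[1] + 1) / fs,
      duration_s = (d[at] - 1) / fs
    )
  } else {
    mat <- t(as.matrix(dat[, chans]))
  }
  recording(mat, fs, channel_labels = chans,
            meta = list(gaps = gaps, source_files = files))
}

#' Write a recording in the patch CSV dialect
#'
#' @param x A `recording`.
#' @param path Output file, or a prefix when `rotate_every_s` is set.
#' @param rotate_every_s Optional rotation period in seconds; when set,
#'   files `<path>_001.csv`, ... are written.
#' @return The written file path(s), invisibly.
#' @export
write_patch_csv <- function(x, path, rotate_every_s = NULL) {
  stopifnot(inherits(x, "recording"))
  df <- tibble::as_tibble(t(x$samples))
  names(df) <- x$channel_labels
  df <- dplyr::bind_cols(tibble::tibble(sample_index = seq_len(ncol(x$samples))), df)
  write_one <- function(d, f) {
    writeLines(sprintf("# fs=%g", x$fs), f)
    readr::write_csv(d, f, append = TRUE, col_names = TRUE, progress = FALSE)
    f
  }
  if (is.null(rotate_every_s)) {
    return(invisible(write_one(df, path)))
  }
  per <- round(rotate_every_s * x$fs)
  starts <- seq(1, nrow(df), by = per)
  files <- vapply(seq_along(starts), function(k) {
    rows <- starts[k]:min(starts[k] + per - 1, nrow(df))
    write_one(df[rows, ], sprintf("%s_%03d.csv", path, k))
  }, character(1))
  invisible(files)
}

#' Read a plain-text hypnogram
#'
#' One stage token (`W`, `N1`, `N2`, `N3`, `REM`, `UNSCORED`) per line, one
#' line per 30-s epoch.
#'
#' @param path File path.
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty hypnogram file: ", path, call. = FALSE)
  bad <- which(!lines %in% STAGE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown stage token '%s' at line %d of %s",
                 lines[bad[1]], bad[1], path), call. = FALSE)
  }
  hypnogram(lines)
}

#' Write a hypnogram as plain text
#' @param hyp A `hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(unclass(hyp), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' CSV with one row per scheduled night: `participant_id`, `group`
#' (`young`/`old`), `night_index`, `recording_path`, `hypnogram_path`,
#' `disposition` (`usable`, `not_worn`, `poor_reference_adhesion`,
#' `bluetooth`) and optional `actigraphy_tst_min`.
#'
#' @param path Manifest CSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(m)) stop("empty manifest: ", path, call. = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("participant_id", "group", "night_index", "disposition")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(m$disposition), DISPOSITIONS)
  if (length(bad)) {
    stop("unknown disposition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(m[, c("participant_id", "night_index")])) {
    stop("duplicate (participant, night) rows in manifest", call. = FALSE)
  }
  if (!"actigraphy_tst_min" %in% names(m)) m$actigraphy_tst_min <- NA_real_
  tibble::as_tibble(m)
}

#' Write a cohort manifest
#' @param m Manifest tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  readr::write_csv(validate_manifest(m), path, progress = FALSE)
  invisible(path)
}
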