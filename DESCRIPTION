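Package: sleepatch
Title: At-Home Wearable Sleep EEG Analysis: Staging Ingest, Event
    Detection, Spectral Summaries and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-night forehead-patch sleep EEG
    recordings. Provides preprocessing (Butterworth band-pass and notch
    filters, polyphase downsampling), covariance-based artifact rejection
    in 5-second windows, a recording-length quality gate with actigraphy
    override, slow-oscillation detection by zero-crossing and amplitude
    percentile rules, sleep-spindle detection by sliding-window RMS
    thresholding, Welch power spectral density with relative band powers
    and a duration-weighted composite NREM delta, multitaper spectrograms
    for quality control, delta-band signal-to-noise ratio, per-night
    macroarchitecture summaries aggregated to per-participant means, a
    data-retention ledger, and Mann-Whitney group comparisons reported as
    centered U with rank-biserial effect sizes and Fisher-z confidence
    intervals. Includes a synthetic polysomnography-like cohort generator
    (1/f background plus stage-specific oscillatory events and injected
    artifacts) with ground truth, so the full pipeline is testable
    without access to recorded human data. EDF, patch-app CSV and
    plain-text hypnogram readers and writers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
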