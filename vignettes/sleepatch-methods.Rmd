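---
title: "Methods: at-home forehead-patch sleep EEG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: at-home forehead-patch sleep EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepatch)
```

## The measurement problem

Wearable forehead patches make it practical to record sleep EEG at home
for a week at a time, at the cost of a sparse montage: two frontal EEG
electrodes, two EOG electrodes, all referenced to an electrode on the
bridge of the nose, sampled at 250 Hz. `sleepatch` implements the full
analysis chain for such recordings: quality control and artifact
rejection, ingestion of per-night hypnograms, detection of the two NREM
microarchitecture events that decline most reliably with age (slow
oscillations and sleep spindles), night-level macro- and
microarchitecture summaries, multi-night averaging to one estimate per
participant, a data-retention ledger, and two-group (young vs old)
Mann-Whitney comparisons reported as centered U with rank-biserial
effect sizes.

Because home deployments lose many nights (detached reference
electrodes, devices not worn, dropped Bluetooth links), data accounting
is part of the method, not an afterthought: every scheduled night
carries a disposition, and the ledger separates participants who
contributed no usable night from those who contributed at least one.

## Per-night processing

The stages run in a fixed order; each is a small exported function so
any stage can be exercised alone.

1. **Quality-control filtering.** Each channel is band-passed 0.3–35 Hz
   and notch-filtered 59–61 Hz, both as 4th-order Butterworth filters
   applied forward and backward (zero phase). The notch runs only at the
   native rate: after downsampling to 100 Hz the mains band is beyond
   Nyquist and is necessarily absent. Filter design comes from
   `signal::butter`; the forward–backward pass is a small compiled
   kernel with odd-reflection padding long enough (six time constants of
   the low cutoff) to absorb start-up transients.
2. **Quality gate.** A night is kept if at least 5 hours of signal were
   actually recorded. "Recorded" excludes dead signal: 5-s windows that
   are flat on every channel — the signature of a detached reference —
   do not count, nor do artifact-flagged windows when a mask is
   available. A short file is still kept when wrist actigraphy
   independently reports under 5 hours of sleep, in which case short
   sleep, not device failure, is the parsimonious reading. Short
   unusable files are tallied with connectivity losses; long-but-garbled
   files with reference-adhesion losses.
3. **Downsampling.** 250 → 100 Hz by Fourier-method resampling
   (spectrum truncation at the new Nyquist). This is exactly
   anti-aliased and has unit passband gain; the installed polyphase
   resampler showed a ~6% gain error at 10 Hz, which would have leaked
   into every band-power estimate downstream.
4. **Artifact mask.** The recording is cut into 5-s windows. Per window
   a single scalar is computed, `log(1e-12 + mean over channel pairs of
   |covariance|)`, then z-scored across the night; windows with |z| > 3
   are excluded from *all* downstream computation (event detection,
   PSDs, SNR, density denominators). The log makes the metric invariant
   to global gain and maps both flatline (covariance collapses) and
   movement bursts (covariance explodes) to large |z|. The choice of a
   single scalar metric is this package's definition; windowed
   interchannel covariance admits several.
5. **Staging.** The supported path ingests a 30-s-epoch hypnogram (AASM
   labels W/N1/N2/N3/REM) scored elsewhere, aligning it to the epoch
   grid (±1 epoch tolerated). A deliberately naive rule-based stager is
   included **only** so synthetic end-to-end tests can run without an
   external scorer; the trained classifier used in practice is a learned
   model and is out of scope here — re-implementing its rules without
   its weights would misrepresent it.
6. **Event detection** (next section), **spectral summaries**, and the
   **macro summary**: total sleep time (0.5 min per sleep-scored epoch),
   time in bed (full recording duration), sleep efficiency
   (100·TST/TIB), and stage percentages of TST.

## Event detectors

**Slow oscillations.** The staging channel is band-passed 0.5–1.5 Hz.
Every pair of consecutive down-going zero crossings bracketing a
negative then a positive half-wave is a candidate; a candidate is kept
if it lies in NREM, overlaps no artifact window, lasts 0.5–2 s between
its bounding down-crossings, and its peak-to-peak amplitude exceeds the
75th percentile of that night's candidate pool. Two points were left
open by the criteria the detector follows and are fixed here as package
definitions: "amplitude" is trough-to-peak (the common SO convention),
and the percentile pool is the night's own candidates on the detection
channel (detection runs per recording, so night-level pooling is the
only self-contained choice). The detector attaches its full candidate
pool to the result so the percentile rule can be audited after the
fact. Note that a pure percentile rule always keeps the top quarter of
candidates: on an event-free recording it will still return "events",
and SO densities are therefore comparable *between* nights processed
identically, not absolute counts.

**Spindles.** The signal is band-passed 12–16 Hz; RMS is computed in
0.3-s windows sliding by 0.1 s. Windows lying in artifact-free epochs
of the target stage (N2 and N3 are scanned separately) form the night's
statistics. The detection threshold is the mean of those RMS values
plus 1.5 standard deviations *of the band-passed signal itself* over
the same epochs. This is the one place the package departs from the
more literal "mean + 1.5 SD of the RMS series": the RMS series is so
heavily smoothed that its own SD compresses the spread to the point
where stationary background noise sustains spindle-length excursions
above threshold several times per minute, which no usable spindle
detector can tolerate (the package's Monte-Carlo benchmark measures
~7/min for the literal rule versus ~0.03/min for the definition used).
Both statistics scale linearly with the signal, so detection remains
invariant to global gain. A spindle is a maximal suprathreshold run
whose span lasts 0.5–2 s; runs may cross boundaries of contiguous
same-stage epochs; a subthreshold dip splits runs (no merging rule is
applied). Densities divide event counts by artifact-free minutes of the
relevant stage(s).

## Spectral estimates

Welch PSDs use 4-s Hann windows with 50% overlap (0.25-Hz resolution,
enough to resolve the 0.5-Hz delta edge). Relative band power
integrates the PSD by the trapezoid rule over delta (0.5–4), theta
(4–8), alpha (8–12) and beta (12–30 Hz) and normalises by the four-band
sum, so fractions add to one by construction. Stage-wise PSDs are
computed on 0.5–45 Hz filtered signal over the concatenated
artifact-free epochs of the stage; the composite NREM delta is the
N2/N3 duration-weighted mean of relative delta. The QC spectrogram uses
Slepian (DPSS) tapers — 6-s window, 0.25-s step, time-halfbandwidth 3,
5 tapers, configurable — computed from the tridiagonal formulation.

Delta-band SNR contrasts sleep against the pre-sleep-onset wake
baseline on the staging channel:
`10·log10(mean sleep delta power / mean pre-onset wake delta power)`,
with sleep onset the first epoch scored anything but W and epoch powers
from per-epoch Welch PSDs of artifact-free epochs.

## Group statistics

Per-participant values (means over usable nights) are compared with
Mann-Whitney tests. The package reports the *centered* statistic
`U_c = U − n1·n2/2` (positive when the young group tends higher), which
is what a table mixing positive and negative "U" values necessarily
contains, and the rank-biserial correlation `r = U_c/(n1·n2/2)`. The
95% CI applies the Fisher z-transform with
`SE = sqrt((n1+n2+1)/(3·n1·n2))`; this specific SE is the one interval
construction that reproduces, to printed precision, every published CI
the package's acceptance suite checks. P-values are exact (from the
null U distribution) when there are no ties and both groups have ≤ 25
observations, otherwise a tie-corrected normal approximation without
continuity correction — half-integer printed U values imply midrank tie
handling, and the exact/approximate switch is the standard convention.
No multiple-testing correction is applied across measures (matching the
analysis the package reproduces); the formatted table footnotes this.

## The synthetic cohort generator

No raw study EEG is publicly deposited, so the generator is the test
bed: it emulates just enough structure for every pipeline stage to be
validated against known ground truth.

* **Hypnograms** come from a semi-Markov night model: an initial wake
  run (mean 7 min), then repeated cycles N1 → N2 → N3 → N2 → REM with
  Poisson dwells, N3 dwell decaying (×0.7 per cycle) and REM growing
  (×1.05), and brief awakenings between cycles. Defaults were set once
  so that young-group stage shares land near 3/59/18/20% (N1/N2/N3/REM
  of sleep time); the old group halves the N3 dwell (returned to N2),
  reproducing the roughly 2:1 young:old N3 ratio reported for this age
  contrast.
* **Signals** are 1/f (power ∝ 1/f) Gaussian background, synthesized in
  the frequency domain and scaled per epoch to a stage-specific RMS (W
  15, N2 20, N3 30 µV …), plus injected events, all logged as ground
  truth: slow oscillations (one 0.75-Hz sine period starting on the
  down-phase, peak-to-peak 150 µV ± 20%, 8/min in N3), spindles
  (Tukey-windowed 12.5–15.5 Hz bursts, 0.5–1.5 s, 3/min in young N2 vs
  1/min in old N2 — mirroring the ~3:1 published density ratio), REM
  eye movements (opposite-polarity EOG deflections), waking alpha, and
  optional movement bursts logged as artifacts. Events never overlap
  within a channel (1-s gap) so ground-truth matching is unambiguous.
* **Data loss** is emulated per disposition: `not_worn` nights produce
  nothing, `bluetooth` truncates the recording, and
  `poor_reference_adhesion` flatlines or garbles the night from a
  random early point onward, which the quality gate then rejects.
* Nights are generated independently; real data have night-to-night
  correlation and first-night effects the generator does not model.

Passing tests on this generator show the pipeline implements its rules
correctly and recovers known effects at realistic amplitudes; they do
not certify detector accuracy on real EEG, where spindle morphology,
1/f slope and artifact structure are richer.

## Numerical choices and benchmark sizes

* Tolerances follow from construction: relative band powers sum to 1 to
  1e-9 (normalisation); EDF round-trips are exact to half a 16-bit
  quantization step; Welch Parseval consistency is asserted at 5% (Hann
  edge effects).
* Degenerate inputs have defined behaviour rather than errors where a
  value is meaningful: a zero-variance artifact metric yields z ≡ 0 (no
  flags); an all-wake night scores TST 0 and efficiency 0 with `NA`
  stage percentages; detectors return empty tables when their stage is
  absent.
* The naive stager's thresholds (relative delta > 0.56 → N3, sigma-RMS
  burst ratio > 2.5 → N2, EOG deflection > 8 MADs with low delta → REM,
  alpha fraction > 0.17 → W, else N1) were tuned once on generator
  seeds 1–6 and are validated in the test suite on held-out seeds.
* Benchmark sizes are the package's standing choices: detector
  benchmarks use twenty 20-minute single-stage nights at 100 Hz; the
  end-to-end group-recovery benchmark uses twenty replicates of a
  12-vs-12 cohort with one 2-hour night per participant at 100 Hz,
  compared on N3% and N2 spindle density. The exact-p property is
  checked against exhaustive permutation for all group sizes up to 7.

## Known limitations

* The SO percentile rule returns relative, not absolute, event sets
  (see above); cross-study comparability of SO density requires
  identical processing.
* Time in bed is the device-observable recording span, so sleep
  efficiency is efficiency over wear time, not over diary bed time; a
  manifest with diary times can substitute.
* The EDF writer emits 1-s records and requires whole-second
  recordings; EDF+ annotations and BDF are out of scope.
* The patch app's CSV dialect (header `# fs=...`, `sample_index` plus
  one column per channel, rotation by file suffix) is this package's
  documented definition of an otherwise unpublished format; gaps are
  reported and sentinel-filled (`NA`), never interpolated.
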