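---
title: "Stimulus-evoked CA1 ensemble dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-evoked CA1 ensemble dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1ensemble)
```

## The analysis problem

Acute hippocampal slices from GCaMP6f-expressing mice are imaged over the
CA1 stratum pyramidale while the Schaffer collaterals are stimulated and a
local field potential (LFP) is recorded in stratum radiatum. Each session
yields a matrix of per-ROI ΔF/F traces (about 100 somatic ROIs × 720 frames
at 7.5 Hz ≈ 96 s), a 20 kHz LFP voltage trace, and 10 stimulus onsets
delivered 10 s apart. The scientific questions are population-level: which
neurons produce calcium transients, how the *ensemble* — the transiently
coactive group — responds in the seconds after each stimulus, and whether
the same neurons participate stimulus after stimulus.

`ca1ensemble` implements that pipeline end to end: transient detection,
fEPSP measurement, calcium/LFP alignment, ensemble-trace construction,
post-stimulus epoch detection, ensemble fraction, Hamming-distance pattern
similarity, and a circular-shift shuffle null, together with a seeded
synthetic-session generator that makes every stage testable without any
recording on disk.

## Event detection

**Detrending.** Slow fluorescence drift (residual photobleaching, focal
drift) is removed by locally weighted regression (`stats::lowess`, robust
iterations on, span 101 frames ≈ 13.5 s by default). Robust iterations keep
sparse transients from pulling the trend; a pure linear ramp is removed to
numerical precision, while a transient a few frames wide is attenuated by
far less than 10%.

**Baseline.** Each ROI's noise model is estimated by iteratively fitting a
Gaussian to the histogram of all data points: Freedman–Diaconis bins, a
least-squares fit of $A\exp(-(x-\mu)^2/2\sigma^2)$ to the bin counts,
censoring of samples above $\mu + 2\sigma$, and refitting until the
relative change in $\sigma$ drops below $10^{-3}$ (cap 20 iterations).
Censoring makes $\hat\sigma$ robust to transient contamination: with 10% of
samples inside large positive transients the fitted $\sigma$ stays within a
few percent of truth while the naive whole-trace SD errs by more than 25%.
The histogram details (bin rule, censor level, tolerance, cap) are not
dictated by the underlying method and are all arguments with the defaults
above.

**The 4 SD / 2 SD rule.** A calcium event is a maximal run of samples above
$\mu + 2\sigma$ containing at least one sample at or above $\mu + 4\sigma$;
start is the first run sample, end the first sample after the run falls
back below the 2 SD bound, peak the argmax. A 4 SD sample anywhere in the
run qualifies (for unimodal transients this is equivalent to requiring it
at the peak). Detection runs on the detrended trace at the native 7.5 Hz —
detecting on interpolated data would manufacture resolution — and event
times are carried into the aligned timebase in seconds. One known
consequence of the run definition at 7.5 Hz sampling: the decaying tail of
a very large transient can hover near the 2 SD bound, briefly dip below it,
and re-cross 4 SD on a noise excursion, splitting off a spurious second
event. Measured over seeded sessions this affects a few percent of planted
8σ events; the detector is left exactly as defined, and the recovery tests
bound the spurious-extra rate (≤ 5%) rather than asserting an exact count.

Per-ROI features are count, frequency (count / duration), onset-to-onset
inter-event interval (defined for ≥ 2 events; peak-to-peak is a
configurable alternative), mean amplitude and duration. A session is valid
only when at least 3 ROIs are active (inclusive, "minimum of 3").

## LFP analysis

Stimulus events are found by threshold search on the rectified,
median-centered LFP with 50 ms refractory merging of nearby crossings. The
fEPSP is measured in a configurable post-stimulus window (default 2–50 ms;
the 2 ms edge blanks the stimulus artifact) against a local pre-stimulus
baseline: peak amplitude is the largest absolute deflection, slope the
linear fit over the 20–80% span of the rising phase toward the peak. The
original measurements were cursor-based; automating them with a fixed
window is the reproducible formalization, and both measures are invariant
to constant offsets. Input/output curves average peak amplitude per tested
intensity (0–90 mA); the test intensity is the smallest intensity whose
mean response lies in the 30–50% band of the maximum, falling back to the
nearest-to-40% intensity with a warning when the band is empty. Post-HFS
responses are normalized by the mean baseline peak, and a slice is flagged
excluded when its mean normalized amplitude across the three post-HFS
sessions (30 s, 5 min, 10 min) is below 1; the source protocol says "the
post HFS session" without singling one out, so the mean across all three is
used. The HFS protocol itself (4 trains, 100 Hz, 1 s, 10 s ISI) is stored
and validated, never delivered.

## Alignment and sweeps

Calcium traces are linearly interpolated from 7.5 Hz to 2 kHz (sample-center
timestamps, no extrapolation); the LFP is decimated from 20 kHz to 2 kHz
after a zero-phase 4th-order Butterworth low-pass at 800 Hz, which preserves
DC, passband amplitude within 1%, and stimulus timing within 0.5 ms. Linear
interpolation is chosen because it is monotone and artifact-free; the
synthetic LFP is filtered even though acquisition hardware already low-passes
real recordings, because the generator's noise is not band-limited. Sweeps
run from each stimulus onset to the next, truncated to a common 10 s grid,
so 10 stimuli produce exactly 9 sweeps — the period after the last stimulus
is not a sweep. The confocal-laser sync pulse used to trim real recordings
is not modeled; an explicit alignment offset in the session metadata plays
that role (default 0).

## Ensemble trace, epochs, and pattern types

On a cell-by-cell basis all values below the ROI's 4 SD event threshold are
set to 0 and the suprathreshold remainder is divided by the ROI's session
maximum, so values lie in [0, 1] and noise never contributes. The ensemble
trace is the across-ROI mean of this normalized matrix — the fraction of
the total active ensemble through time. (Because linear interpolation
commutes with the across-ROI mean, the pipeline computes the ensemble trace
at the native rate and upsamples the one-dimensional signal; the result is
identical to upsampling every ROI first.)

Averaged sweeps show up to three post-stimulus features: a first ensemble
maximum (usually < 1 s), an ensemble minimum (1–3 s), and a second maximum
(within 5 s). Extremum search runs on the averaged sweep after a 50 ms
moving average, with maxima required to clear a prominence floor of 10% of
the sweep's dynamic range — raw interpolated traces are piecewise linear
and otherwise produce spurious micro-extrema; ties go to the earliest
candidate. The minimum needs different handling because suppression
produces a *flat* valley rather than a point minimum: its latency is the
midpoint of the longest run of near-minimal values (within 1% of the
dynamic range of the minimum) inside the search window. The 1% plateau
tolerance is set between the contribution of a single isolated event
(≈ 1/(n_ROIs × n_sweeps) of one ROI's normalized amplitude, well below it)
and typical spontaneous coverage outside the valley (well above it), so
isolated blips neither break the valley nor extend it.

Ensemble fraction is the fraction of ROIs whose event interval intersects
the 10 ms window centered on the epoch time, applied at each stimulus using
the session-level (averaged-sweep) epoch latency; interval overlap is the
only meaningful activity notion at 7.5 Hz native sampling. Sessions are
typed from the epoch combination at the highest stimulus intensity: Type A
(first maximum dominant, with a minimum), Type B (second maximum dominant
or alone, with a minimum), Type C (minimum only). The A/B amplitude
comparison formalizes what was originally a visual judgment; the rule is
stated in `classify_pattern()` and is deliberately simple.

## Similarity and the shuffle null

Per epoch and stimulus, the active-ROI pattern is a binary vector; ensemble
distance is the mean normalized Hamming distance over all stimulus pairs.
Hamming distance is used precisely because two all-zero patterns — routine
during the ensemble minimum — have distance 0, where Jaccard and cosine are
undefined. Normalizing by ROI count keeps slices with different ensemble
sizes comparable.

The chance model rotates each ROI's activity independently on the circle of
the recording (1,000 iterations by default) and recomputes ensemble
fraction and distance at the epoch times observed on the real data. Epoch
times are held fixed rather than re-detected per shuffle: the question the
null answers is "how much activity would land in *these* windows by
chance", and fixing the windows makes the null stable and interpretable.
The implementation rotates the detected event intervals (mod the recording
duration) instead of rotating the trace matrix and re-detecting — the same
operation applied after detection, which preserves per-ROI event counts
exactly and makes 1,000 iterations cheap. Shift amounts are drawn as one
seeded `n_shuffles × n_ROIs` matrix, so the null is bit-reproducible from
the configuration seed. A subtlety worth knowing when calibrating the null:
evaluating the observed fraction at an epoch time *detected on the same
data* is a selection effect (the time was chosen because activity peaked
there), so calibration experiments on stimulus-unlocked sessions evaluate
both the observed value and the null at a fixed nominal latency instead.

Conservation under rotation is exact in exact arithmetic but floating-point
summation is order-sensitive in the last bit, so the package exposes
`trace_time_average()`, which sums sorted values and is therefore exactly
rotation-invariant; the conservation tests use it.

## The synthetic-data generator

`generate_session()` emulates one recording at the study's geometry — 50
ROIs × 720 frames at 7.5 Hz, 10 stimuli 10 s apart starting at 2 s, 20 kHz
LFP — with:

* i.i.d. Gaussian baseline noise (SD 0.02 ΔF/F) plus a slow decaying
  drift (amplitude 0.05, time constant 40 s) standing in for residual
  bleaching;
* transients shaped by a difference of exponentials (rise 50 ms, decay
  300 ms, peak 6× noise SD with 10% lognormal jitter) — representative
  GCaMP6f kinetics, evaluated in continuous time at frame centers so
  sub-frame phase is preserved;
* spontaneous events as a per-ROI Poisson process (default 0.1 Hz, a
  plausible slice-level somatic rate);
* a three-epoch evoked structure: core ensembles (60% of ROIs for epoch 1,
  30% for epoch 3) whose members fire per stimulus with reliability
  `p_repeat` (default 0.9; non-members leak at 0.02), evoked latencies
  placed so the transient *peak* lands at the programmed epoch time
  (0.4 s and 3.5 s) with 30 ms jitter, and complete suppression of
  spontaneous events inside the 1.6 s window centered at 1.8 s. Suppression
  silences suprathreshold activity throughout the window, so events whose
  transient would still be elevated inside it — onsets up to one transient
  envelope before the window — are thinned as well; without that lead the
  programmed valley starts late and its measured center is biased;
* an LFP with a one-sample 5 mV artifact spike at each onset and a
  negative alpha-function fEPSP (0.5 mV, τ = 5 ms, 3 ms delay);
* group profiles: sham-like (base rates) and HFHI-like (spontaneous rate
  × 1.5, membership reliability × 0.7), emulating the elevated transient
  rate and degraded coordination of the head-impact group.

The generator reproduces the statistical structure the analysis assumes —
Gaussian noise with slow drift, kernel-shaped transients, stimulus-locked
ensembles with repeating membership — and deliberately not the things the
pipeline does not consume: pixel-level movies, motion artifacts,
neuropil contamination, correlated noise across ROIs, or biophysical
calcium buffering. Tests passing on synthetic sessions therefore validate
the pipeline's logic and calibration, not the upstream extraction steps
(which are out of scope), and the generator's spontaneous rates are
placeholders for recovery testing, not estimates of the study's values.

## Numerical choices and degenerate inputs

* Times are seconds, t = 0 at recording start, timestamps at sample
  centers; this removes 0/1-based frame ambiguity.
* CSV payloads are written with `%.17g`, so write/read round trips are
  bit-identical.
* Constant traces are degenerate for baseline fitting and raise an error;
  all-subthreshold ROIs normalize to all-zero rows; an absent epoch yields
  missing values, never zeros.
* QC thresholds are inclusive ("maximum 2.2" admits 2.2); the area range is
  closed. Baseline drift and stability are defined against window medians
  and are meaningful on raw-fluorescence-scale traces (as produced by
  upstream extraction tools), not on zero-centered ΔF/F. The upstream
  definitions of roundness, oblongness, and "baseline stability of 1,000"
  are tool-internal; the package states its stand-ins (isoperimetric
  ratio from the traced boundary; second-moment axis ratio with pixels as
  unit squares; inverse coefficient of variation of 100-frame window
  medians) and makes every threshold configurable.
* Quartiles for the 1.5×IQR outlier rule are Tukey hinges
  (inclusive-median); the flags depend on this choice, so it is fixed and
  documented.
* Equal-prominence epoch maxima resolve to the earliest candidate.

## Problem sizes used by the test and acceptance runs

The shipped tests run the full pipeline at the study geometry: 20 seeded
sessions for epoch/pattern recovery, 100 stimulus-unlocked plus 20 evoked
sessions for null calibration (200-iteration nulls in the test suite,
1,000 in `scripts/acceptance.R`), 20 paired seeds for reliability
discrimination, and 20 sessions per group for the rate-effect cohort.
These sizes give binomial standard errors comfortably inside the asserted
bands while keeping a full run in minutes.

## Known limitations

* The pipeline starts from extracted ΔF/F traces; ROI extraction, bleach
  and motion correction are upstream and out of scope.
* Statistical inference (mixed-effects models, post hoc comparisons) is
  deliberately not included; `summarize_cohort()` emits tidy tables for
  external tools.
* Only positive-going transients are detected; dendritic ROIs and
  behavioral covariates are out of scope.
* The HDF5 container variant of the session format is not provided; the
  CSV dialect is the interchange format.
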