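---
title: "Methods: validating PPG pulse rate variability against ECG heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating PPG pulse rate variability against ECG heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prvagree)
```

## Scope and model

`prvagree` implements a device-validation workflow for pulse rate
variability (PRV): paired interbeat-interval streams from a PPG sensor and
an ECG reference, recorded simultaneously over two five-minute tasks (rest
and a mental stressor), are aligned, cleaned, reduced to nine short-term
HRV metrics, and compared with a multi-method agreement battery plus a
paired task contrast. Because the workflow must be testable without any
recorded data, the package ships a synthetic cohort generator whose
defaults encode the emulated study conditions; all acceptance-style checks
run against that generator's ground truth or against published summary
statistics.

### The interval model

Interbeat intervals are modelled directly at the interval level:

$$RR_i = \mu + a_{LF}\sin(2\pi f_{LF} t_i) + a_{HF}\sin(2\pi f_{HF} t_i + \varphi) + \varepsilon_i,$$

with $t_i$ the cumulative beat time at the start of interval $i$,
$\varepsilon_i$ white noise, and $\varphi$ drawn uniformly once per series.
This is a deliberate simplification relative to integral
pulse-frequency-modulation models: the band powers of pure sinusoidal
modulation are analytically $a^2/2$, which gives the spectral stage an
exact oracle. The cost is realism — real RR series have broadband 1/f-like
structure, respiratory sinus arrhythmia that is frequency-modulated by
breathing, and nonstationarity. Passing tests on this generator therefore
demonstrate correctness of the computational pipeline, not performance on
real recordings.

Defaults (per subject, rest condition): mean interval 780 ms, LF modulation
35 ms at 0.10 Hz, HF modulation 28 ms at 0.25 Hz, interval noise 10 ms.
These produce pooled means near 770–780 ms, SDNN near 33–45 ms and LF/HF
powers of a few hundred ms² — the magnitudes typical of seated healthy
adults. The stress condition multiplies the mean interval by 0.95 and every
amplitude by 0.85 (shorter intervals, reduced variability), the direction
and rough size of mental-stressor effects on short-term HRV.

Between-subject structure is required for cohort-level agreement
statistics: with identical subjects, Lin's concordance degenerates (zero
between-subject variance makes the coefficient meaningless) and
Bland–Altman SDs collapse to estimation noise. Subject-level mean intervals
are drawn with SD 60 ms and modulation amplitudes log-normally with CV
0.25; both knobs are exposed in `synthetic_config()`.

### The PP channel and PTT jitter

The PPG-like channel is derived from the RR ground truth by adding an
independent Gaussian pulse-transit-time term $\eta_i$ (SD
`ptt_jitter_sd`) to each pulse arrival, so

$$PP_i = RR_i + \eta_{i+1} - \eta_i.$$

The first-difference structure is the scientific heart of the generator:
summing telescopes, so total duration changes only by $\eta_{n+1}-\eta_1$,
and

$$\mathrm{RMSSD}(PP)^2 \approx \mathrm{RMSSD}(RR)^2 + 6\sigma^2,
\qquad \mathrm{SDNN}(PP)^2 \approx \mathrm{SDNN}(RR)^2 + 2\sigma^2,$$

because successive PP differences accumulate three independent jitter
terms. Short-term metrics (pNN50, RMSSD, HF) are therefore inflated far
more, in relative terms, than SDNN/LF/SD2 — reproducing the overestimation
pattern reported for earlobe and wrist PPG against ECG. Both identities are
verified by Monte-Carlo tests.

No quantitative PTT model is available to copy, so the jitter SD is a
calibration knob. A sweep over 4–10 ms showed the same qualitative pattern
throughout; the default of **8 ms** was chosen because it reproduces the
published qualitative reading most faithfully: RMSSD|SD1 falls below the
0.95 concordance threshold (poor agreement) while the mean interval, LF and
SD2 stay at almost-perfect concordance and good BA ratios, SDNN sits in
between, and HF agrees worse than LF by both criteria. Smaller values
(≈4 ms) match the published RMSSD concordance magnitude more closely but
separate the metric classes only marginally; the default favours the robust
pattern over any single printed magnitude, which the battery never asserts
numerically.

Device lag is emulated by dropping up to 3 leading beats from one channel;
artifacts are injected at rate 0.002 per interval on the PP channel (half
that on RR, reflecting the cleaner ECG chest-strap signal), alternating
between out-of-range values and 30–60 % in-range spikes, so the observed
error rates land in the 0.1–0.6 % range of good-quality recordings.

## Beat detection

`detect_pp_intervals()` re-implements the sensor's on-board chain:
2nd-order Butterworth low-pass at 5 Hz, first derivative (forward
difference × fs), squaring, dynamic-threshold peak picking. Choices the
firmware description leaves open, and how they were resolved:

- **Zero-phase filtering.** The offline filter runs forward and backward
  (reflection-padded, because a plain forward–backward pass without padding
  shows large edge transients). The firmware filter is causal; the
  resulting beat-time offset is constant and cancels exactly in intervals.
- **Dynamic threshold** = 0.3 × rolling maximum of the squared derivative
  over a centred 2 s window, recomputed per sample (O(n) blockwise
  prefix/suffix maxima). The fraction matters: squaring doubles relative
  amplitude variation, so with ±20 % pulse-amplitude swings a weak beat
  adjacent to a strong one reaches only ~0.44 of the local maximum — a 0.5
  threshold provably drops such beats, 0.3 leaves headroom while still
  rejecting filtered noise. The threshold is relative, making detection
  invariant to any positive rescaling of the waveform (tested).
- **Refractory rule: keep the first peak** within 350 ms (the lower
  physiological plausibility bound). After 5 Hz smoothing the rising- and
  falling-edge derivative peaks of a pulse are nearly equal, and a
  "keep the larger" rule lets noise flip between edges (±100 ms beat-time
  errors); the systolic upstroke always precedes the decay, so keeping the
  first candidate locks onto it deterministically.

On synthetic waveforms (raised-cosine pulses with a fast 30 %-width
upstroke, SNR 10, ±20 % amplitude variation) the detector achieves F1 = 1.0
at ±50 ms matching tolerance over 20 seeds; clean waveforms are recovered
within 2 ms. These figures are upper bounds for real PPG, whose morphology
(dicrotic notch, baseline wander, motion artifacts) the generator does not
model.

## Alignment

The devices share no clock, so series are aligned by integer beat lag:
Pearson correlation of the overlapping segments is computed for every lag
in ±15 beats (default) and the maximizing lag is chosen. The variance of
the element-wise differences is the tie-breaker, then the smaller absolute
lag. The original description names both minimum variance and maximal
cross-correlation without an arbitration rule; correlation-first is the
deterministic choice made here, and the whole rule is pinned by an
exhaustive brute-force oracle in the tests (50 random instances) plus a
claimed ≥95 % recovery rate over 200 jittered trials (measured: 100 %).
Sub-beat clock alignment is unobservable from intervals alone and out of
scope. A minimum overlap of 30 beats guards against spurious
high-correlation matches on short segments.

## Artifact QC

An interval is abnormal if outside 350–1350 ms ("range") or if it deviates
strictly more than 20 % from the mean of its two neighbours ("deviation").
Resolved ambiguities:

- **Single pass, original neighbours.** Flags are computed once against the
  uncorrected series, then repaired — no iterative re-flagging. A
  consequence worth knowing: an out-of-range artifact *always* drags its
  in-range neighbours over the 20 % bound (the neighbour mean is pulled
  past it), so a lone spike can produce three flags. The repair
  interpolates across the whole flagged run, which is the right behaviour.
- **Strictly greater than 20 %**: a deviation of exactly 20 % is not
  flagged (boundary covered by a dedicated test).
- **Edge intervals** have no two neighbours and are tested by the range
  rule only.
- Runs of flags are repaired by linear interpolation between the nearest
  clean values; runs touching a series end have no anchor and are trimmed,
  reported as unrepairable spans — matching how terminal recording gaps
  must be handled in practice.

Sensitivity is 1.0 by construction for out-of-range injections (tested);
for in-range deviation spikes it is measured, not asserted, because
adjacent corruptions can mask one another.

## HRV features

Nine metrics per record: mean interval, SDNN, pNN50, RMSSD, LF, HF, LF/HF,
SD1, SD2. Conventions chosen where the field varies:

- **SDNN** uses the sample (n−1) denominator.
- **pNN50** counts successive differences strictly greater than 50 ms.
- **SD1 ≡ RMSSD/√2** exactly: the mean successive difference is treated as
  zero (it telescopes to $(x_n - x_1)/(n-1)$, negligible for any real
  record), which makes the identity hold to machine precision and is
  asserted at 10⁻⁹ relative tolerance on every input. SD2 is the population
  SD of $(x_i + x_{i+1})/\sqrt2$, verified against an explicit
  rotation-matrix oracle.
- **Spectra** use a hand-implemented classical (tau-shifted) Lomb–Scargle
  periodogram on the cumulative beat times — no resampling — over the fixed
  grid 0.003–0.4 Hz in 0.0005 Hz steps; an interval is assigned to the time
  of its terminating beat. The periodogram is rescaled so its trapezoidal
  integral over the full grid equals the sample variance, making band
  integrals absolute powers in ms² (LF 0.04–0.15 Hz, HF 0.15–0.4 Hz; the
  VLF part of the grid is computed but not reported, as appropriate for
  five-minute records). Absolute band powers are convention-dependent
  across implementations, so golden tests use analytic sinusoids
  ($a^2/2$, recovered within 10 %) and a least-squares sinusoid-fit oracle,
  never published LF/HF magnitudes. When HF is exactly zero the LF/HF
  ratio is reported as `NA`, not infinity.

## Agreement battery

Per metric, across subjects, PPG device minus ECG reference (this sign
convention makes the short-term biases positive — the PPG side
overestimates):

- **CV difference**: CVs from the across-subject means and SDs of the
  metric.
- **Hedges's g**: mean difference over the (n−1)-weighted pooled SD, times
  J = 1 − 3/(4N − 9). The summary-statistics path and the raw-sample path
  are one function, so they agree to machine precision by construction;
  this path reproduces all six derivable published effect-size cells to 3
  decimals.
- **Lin's concordance** with population (1/n) moments. Reported as
  unavailable when either variable fails Shapiro–Wilk at p ≤ 0.05
  (mirroring the "-" cells of the published tables); the conservative label
  scheme collapses McBride's substantial/moderate span and calls anything
  below 0.95 poor. Identical constant series are perfect agreement by
  convention; one-sided zero variance is an error.
- **Bland–Altman**: bias, sample SD of differences, LoA = bias ± 1.96·SD,
  bias CI via $t_{0.975,n-1}\,s/\sqrt n$, LoA CIs via the classical
  $t\,s\sqrt{3/n}$ approximation (no published CI exists to pin an
  alternative). Difference-normality is reported but does not gate — the
  parametric analysis proceeds regardless, as is standard practice when no
  non-parametric reference limits exist. BA ratio = (1.96·SD)/(mean of the
  two method means); labels good < 0.1 ≤ moderate < 0.2 ≤ poor, the
  boundary 0.1 itself falling to moderate.

Two published columns are deliberately excluded from golden tests: the
mean-interval BA ratios (printed 0.005, but the stated formula applied to
the printed cells yields ≈0.001 — flagged, not "corrected") and the CV
difference column (not reproducible from rounded printed means/SDs).
BA-ratio golden cells are restricted to the seven whose printed inputs carry
enough precision to reproduce exactly.

## Task comparison

Per device, rest vs stress, over mean interval, SDNN, pNN50, RMSSD, LF, HF,
LF/HF and SD2 (SD1 is excluded as redundant with RMSSD; LF/HF is included
because absolute LF and HF alone can mislead). The paired Wilcoxon signed
rank drops zero differences, then uses full 2ⁿ sign enumeration (midranks)
for up to 12 nonzero differences — exactness survives ties, which the
standard algorithm cannot offer — the standard exact distribution for 13–25
untied differences, and the normal approximation with continuity correction
beyond. Both exact paths are pinned to a brute-force enumeration oracle.
Direction is the sign of the median paired difference. The common-language
effect size is computed over all cross pairs with ties counted half, which
guarantees CLES(x,y) + CLES(y,x) = 1 exactly. No multiple-testing
correction is applied, matching the reference analysis; this is a
documented property, not an oversight. Box-plot summaries follow the
quartile ± 1.5·IQR whisker convention.

## Problem sizes and calibration checks

Chosen problem sizes for the simulation-based checks (the package's own
balance of precision against run time): 18-subject cohorts with five-minute
records for the agreement-pattern check over 10 seeds (requiring the
pattern and the positive short-term bias in ≥90 % of seeds); 200 trials for
lag recovery; 20 seeds for detector F1; 50 seeds × ≥5000 beats for the
jitter-inflation identities; and 1000 cohort draws with 120 s records and
time-domain metrics for the type-I calibration of the rest-vs-stress test
(spectral metrics are excluded from that loop — their estimator is
identical machinery and would multiply the run time roughly tenfold without
changing what is being calibrated). Measured rejection rates under the null
generator fall within 3–7 % at the nominal 5 % level.

## Known limitations

- The generator's sinusoid-plus-noise intervals lack 1/f structure,
  respiratory frequency modulation, ectopy patterns and nonstationarity;
  agreement magnitudes on real data will differ from the synthetic ones.
- The PPG template is a smooth unimodal pulse; no dicrotic notch, baseline
  wander, or motion artifacts, so detector scores are upper bounds.
- The dynamic-threshold and refractory rules are documented stand-ins for
  unpublished firmware logic, validated only on synthetic waveforms.
- Published LF/HF band powers are not reproducible in absolute terms
  without knowing the original normalization; the package's normalization
  (band integrals summing to the sample variance) is self-consistent and
  unit-correct but not unique.
- Whole-beat lag alignment cannot correct sub-beat clock drift.
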