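---
title: "Noninvasive ICP waveform analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive ICP waveform analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicpw)
```

## The problem

The intracranial pressure (ICP) pulse carries three sub-peaks per cardiac
cycle: P1 (percussion wave, arterial ejection), P2 (tidal wave, blood volume
spreading through the brain) and P3 (dicrotic wave). In a compliant
intracranial compartment P1 dominates; as compliance is exhausted the tidal
wave grows and the P2/P1 amplitude ratio rises above 1. Skull-deformation
sensors record a waveform equivalent in shape to the invasive ICP pulse but
in arbitrary units, so absolute pressure is not available — morphology is.
`nicpw` implements the full chain from such a raw pulsatile recording to the
session-level P2/P1 ratio, the session mean ICP (mICP, when a co-recorded
invasive channel exists), the brain compliance index

$$\mathrm{BCI} = \mathrm{mICP} \times \mathrm{P2/P1},$$

threshold classifications (intracranial hypertension mICP > 20 mmHg,
elevated ratio > 1.2, elevated BCI > 19.3; all strict, so boundary values
classify negative), and the diagnostic-accuracy statistics used to relate
these indices to intracranial hypertension and short-term outcome.

## Pipeline model

1. **Filtering** (`preprocess_signal`): zero-phase 2nd-order Butterworth
   band-pass, 0.5–15 Hz. The lower edge removes DC and respiratory-band
   baseline drift; the upper edge keeps the harmonics that shape P1/P2.
   Even-reflection padding is applied before the forward–backward pass:
   without padding the filter's edge transients both bury a trough sitting
   at the record edge and fabricate spurious dips; even (not odd)
   reflection preserves an extremum at the edge.
2. **Onset detection** (`detect_onsets`): the beat period is estimated from
   the autocorrelation peak in the 0.33–2 s lag band, taking the smallest
   near-maximal peak — under beat-to-beat jitter the lag of *two* beats can
   otherwise edge out the fundamental, halving the detected beat count.
   Candidate troughs (local minima of a lightly smoothed copy) are accepted
   deepest-first under a refractory window of 0.6× the period (never below
   0.33 s), refined within ±5% of the cycle, and screened for depth
   consistency against the median trough level. All thresholds are
   relative, which is what makes the pipeline invariant to the gain and
   offset of an arbitrary-unit sensor.
3. **Segmentation** (`segment_pulses`): trough-to-trough, half-open
   `[onset, end)` in 1-based sample indices; the onset trough is the
   natural amplitude baseline for peak measurement. Each beat is assigned
   to the session minute containing its onset; the trailing partial beat is
   dropped.
4. **Quality control** (`filter_pulses`): each beat, resampled to a common
   100-point normalized time base (latency quantization 1% of the cycle),
   must correlate at least 0.8 with the pointwise-median pulse of its
   minute and keep its peak-to-trough amplitude within [0.3×, 3×] the
   minute's median. Motion artifacts fail the amplitude band; distorted
   beats fail the correlation. A single-beat minute is accepted by
   convention. The thresholds are defaults in `analysis_config()`, not
   constants.
5. **Ensemble averaging** (`average_by_minute`): accepted beats are aligned
   to the minute's median template by cross-correlation over ±6 points
   before the pointwise mean (coherent averaging). Without alignment,
   residual onset-timing jitter of a few samples convolves the average with
   the timing-error distribution and selectively attenuates the narrow P1
   peak — we measured this as a +0.02–0.03 bias on the ratio at realistic
   noise. A minute is valid only with ≥ 30 accepted beats (half the beats
   of a typical minute); invalid minutes are excluded from session
   aggregation rather than raising errors.
6. **Morphology** (`locate_peaks`): the averaged pulse is lightly denoised
   with a cubic Savitzky–Golay filter (9 points) — peak-preserving, unlike
   a moving average, and necessary because taking the *highest* local
   maximum of a noisy curve is a max-selection bias that inflates both
   amplitudes. P1 is the highest local maximum at 5–28% of the cycle, P2 at
   28–60%, P3 (reported, never used in any index) at 60–90%; amplitudes are
   measured above the onset value, making the ratio offset-free. When a
   window holds no local maximum, a shoulder — zero-crossing of the second
   derivative after 5-point smoothing — stands in (the common "P1 rides on
   the P2 upstroke" morphology); failing that, the window maximum is used
   and the estimate flagged `merged-fallback`. Ties go to the earlier
   latency. The windows come from the physiological ordering of the three
   waves and are configurable.
7. **Session metrics**: the session P2/P1 is the arithmetic mean of the
   per-minute ratios over valid minutes (median available via
   `session_stat`; whether mean or median is the better session statistic
   is genuinely open, and the mean was chosen as the default for linearity
   with the per-minute averaging). mICP is the mean of per-minute ICP
   means.

## The synthetic generator

No public recordings of cranial-deformation waveforms exist, so the
generator is a first-class, tested module rather than a fixture.

**Pulse model.** One beat is the sum of three Gaussian components
$\sum_i A_i \exp(-(t-\mu_i)^2/2\sigma_i^2)$ with latencies and widths as
fractions of the beat, so morphology is heart-rate invariant. Gaussians were
chosen over gamma or raised-cosine kernels: smooth, analytic, two parameters
per peak, and the functional form of the real pulse is not otherwise
constrained. Because overlapping components shift the extrema, ground truth
is defined as the *achieved* morphology — the summed curve's peak values
read off a dense grid — not the component amplitudes; the recording's
`true_p2p1` is measured on the periodic steady-state waveform (neighbouring
beats' tails included), since that is the pulse a trough-to-trough segment
actually contains. The default latencies (0.14, 0.32, 0.64) and widths
(0.05, 0.09, 0.20) are phased so the concatenated waveform's diastolic
trough falls at the beat boundary (within 0.3% of the cycle): the dicrotic
tail is still decaying when the next upstroke begins, as in real pulses, so
troughs are sharp and detectable. `pulse_shape_for_ratio()` solves the
tidal-wave amplitude for any target achieved ratio; the presets target 0.9
(good compliance) and 1.3 (poor compliance, with the tidal wave delayed to
0.38 so P1 remains resolvable).

**Session model.** Beats are concatenated with per-beat duration
$60/\mathrm{HR}_k$, $\mathrm{HR}_k$ jittered at 3% relative SD; a warm-up
beat before $t = 0$ puts the first trough in steady state. Disturbances:
sinusoidal baseline drift (0.25 Hz, amplitude 0.5 — half the pulse
amplitude), white noise (SD 0.08, ≈ 6% of the pulse range), and motion
artifacts as 0.3-s half-sine transients of 5× the pulse amplitude at
Poisson times (default 1/min) — the simplest event model that exercises QC
rejection. The co-recorded invasive channel is
`micp + scaled mean-centred pulse + noise`, so per-minute means recover the
true mICP to within 0.5 mmHg. Defaults are a 600-s session at 200 Hz
(the device's rate is not public; 200 Hz is assumed and configurable) and
72 bpm, which keeps a 10-minute session above 700 beats even with jitter.
Every simulator call uses one seeded local RNG stream and restores the
caller's RNG state.

What the generator does **not** emulate: the sensor's mechanical transfer
function, hemodynamic (Windkessel-type) pressure–volume coupling, waveform
nonstationarity within a session, arrhythmia, and real artifact zoology.
Passing recovery tests therefore shows the pipeline is correct *for signals
of this class*, not that it is validated on patient data.

**Cohort model.** Session mICP is log-normal — clinical mICP summaries are
right-skewed — fitted to the quartile triple 14 (11–19) mmHg by matching
the median exactly (`meanlog = log 14`) and the log-scale IQR
(`sdlog = (log 19 − log 11)/(2 z_{0.75}) = 0.405`), which puts about 19% of
patients above 20 mmHg. The session ratio follows the linear link
$\mathrm{P2/P1} = 0.82 + 0.02\,\mathrm{mICP} + \varepsilon$, truncated to
[0.4, 2.2]. The residual SD is derived from the correlation identity
$r = b\sigma/\sqrt{b^2\sigma^2 + \sigma_e^2}$ at the target $r = 0.49$ with
$\sigma = 6.42$, the fitted log-normal's own SD — using the distribution's
true SD (rather than a normal-theory IQR approximation, which gives
$\sigma \approx 5.9$) keeps the identity exact for the values actually
sampled; the derived $\sigma_e = 0.228$. Truncation moves the realized
correlation by well under 0.05 (the bounds sit ≈ 3–4 residual SDs from the
bulk).

**Binormal score calibration.** To study operating points without waveform
simulation, `calibrate_binormal()` finds two normal score distributions
reproducing a target AUROC (0.88), sensitivity (0.85) and specificity
(0.77) at the 1.2 cutoff. Three equations, four unknowns: the
negative-class SD is fixed at 0.15, chosen to keep negative-class ratios in
a physiologic band around the cutoff. The AUC equation can admit two
positive-SD roots; the solver takes the root on the decreasing branch of
$\mathrm{AUC}(\sigma_{pos})$ beyond its maximum — the wider-positive-class
solution ($\mu_{neg} = 1.089$, $\mu_{pos} = 1.880$, $\sigma_{pos} = 0.656$),
reflecting the greater heterogeneity of the hypertensive class. Residuals
are checked to 1e-8.

## Statistics

AUROC is the tie-aware Mann–Whitney concordance. Confidence intervals and
paired comparisons use the DeLong placement-value variance, implemented
directly (it is cross-checked against an independent implementation and a
stratified bootstrap in the tests). Sensitivity and specificity at the
strict cutoffs carry Wilson intervals — better small-sample behaviour than
Wald and less conservative than Clopper–Pearson. Categorical cohort
comparisons dispatch between Pearson chi-square *without* continuity
correction and Fisher's exact test on the all-expected-counts ≥ 5 rule;
continuous comparisons dispatch between one-way ANOVA (+ Tukey HSD) and
Kruskal–Wallis (+ Dunn's test with Bonferroni) on a per-group Shapiro–Wilk
screen at α = 0.05, with pure-tie data short-circuited to p = 1. The
AUC-based sample size uses the Hanley–McNeil exponential-approximation
variance under both hypotheses and an integer search; it is verified by a
seeded power simulation at the returned n and just below it.

## Numerical and design choices

- 1-based, half-open `[onset, end)` sample indexing (idiomatic R; all
  fencepost contracts hold unchanged).
- Strict `>` positivity at every printed cutoff; boundary values classify
  negative. Cutoffs, QC thresholds and windows all live in
  `analysis_config()` for sensitivity analyses, including the
  decompressive-craniectomy exclusion rerun.
- Degenerate inputs are contracts, not surprises: flat signals raise a
  no-pulses error, a zero-accepted minute yields an invalid row, perfect
  separation collapses the DeLong CI to a flagged point, a constant vector
  is a correlation error, P1 amplitude of zero is an undefined-ratio error.
- An arterial-blood-pressure-synchronized variant of the ratio algorithm
  (as used by the clinical device) cannot be reconstructed from public
  information and is deliberately not guessed at; the trough-anchored
  estimator here is self-contained.

## Problem sizes

The test suite simulates 10-minute sessions at 200 Hz (120 k samples,
~700 beats) for end-to-end checks, 200 seeded replicates for the
parameter-recovery rate (true session ratio within ±0.05 in ≥ 95% of
default-noise sessions), 125 noiseless shapes for the morphology-vs-oracle
sweep (agreement within 0.02), cohorts of 2000 for quartile and correlation
calibration and 10^5 for the correlation identity, and 2000–3000 Monte
Carlo replicates for bootstrap, coverage and power checks.

## Limitations

Single-session, single-channel analysis only: no beat-by-beat morphology
time series, no alarms, no multivariable outcome modelling, and no claim
that synthetic-data calibration transfers to any particular device. The
session statistic, QC thresholds and peak windows are defensible defaults,
not learned parameters; on real data they should be revisited against
annotated beats.
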