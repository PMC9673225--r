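# nicpw

Analysis of noninvasive intracranial pressure waveforms (NICPW):
pulsatile cranial-deformation recordings carry the same three-peaked
cardiac pulse as invasively measured ICP — P1 (percussion wave), P2 (tidal
wave), P3 (dicrotic wave) — but in arbitrary units. As intracranial
compliance is exhausted the tidal wave grows, so the **P2/P1 amplitude
ratio** is a pressure-free marker of the brain's volume-buffering reserve,
and coupled with the session mean ICP it yields the **brain compliance
index**

    BCI = mICP × P2/P1.

`nicpw` is for researchers in neurocritical-care monitoring who need a
tested, reproducible path from a raw single-channel recording to these
indices and to the diagnostic-accuracy statistics that relate them to
intracranial hypertension (IHT, mICP > 20 mmHg) and short-term outcome:

- **Pulse pipeline** — zero-phase 0.5–15 Hz band-pass, autocorrelation-
  guided trough detection, trough-to-trough segmentation, per-minute
  quality control (template correlation ≥ 0.8, amplitude band), coherent
  ensemble averaging on a 100-point normalized time base.
- **Morphology** — P1/P2/P3 localisation with shoulder and merged-pulse
  fallbacks; session P2/P1 pooled over QC-valid minutes; invariant to the
  gain and offset of the sensor.
- **Session metrics** — mICP (mean of per-minute means), BCI, strict
  threshold classifications (> 20 mmHg, > 1.2, > 19.3).
- **Diagnostics** — tie-aware Mann–Whitney AUROC, DeLong CIs and paired
  AUROC comparison, sensitivity/specificity with Wilson intervals at fixed
  cutoffs, Youden-optimal cutoffs, chi-square/Fisher and ANOVA/Kruskal–
  Wallis cohort comparisons with post hoc tests, Hanley–McNeil AUC sample
  size.
- **Synthetic data** — a seeded generator for three-peak pulse recordings
  (heart-rate jitter, drift, noise, motion artifacts, co-recorded invasive
  channel) and patient cohorts with known ground truth, calibrated so the
  simulated mICP quartiles, mICP–P2/P1 correlation and P2/P1 operating
  points match published cohort summaries.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods and `autoplot()` for sessions and ROC curves.

## Worked example

Simulate a 10-minute poor-compliance session with a true mean ICP of
23 mmHg, then analyse it end to end:

```r
library(nicpw)

sim <- simulate_recording(session_sim_params(
  shape = preset_shape("poor-compliance"),   # achieved P2/P1 ratio 1.3
  micp_mmhg = 23, seed = 42))

fit <- analyze_recording(sim)
fit
#> <nicpw_session>
#>   valid minutes: 10/10 (683/719 beats accepted)
#>   session P2/P1: 1.311; mICP: 23.0 mmHg; BCI: 30.2 mmHg
glance(fit)
#> # A tibble: 1 × 7
#>    micp  p2p1   bci n_valid_minutes iht   p2p1_high bci_high
#>   <dbl> <dbl> <dbl>           <int> <lgl> <lgl>     <lgl>
#> 1  23.0  1.31  30.2              10 TRUE  TRUE      TRUE
```

All 10 minutes passed quality control (683 of 719 detected beats
accepted); the session ratio 1.311 recovers the template's true achieved
ratio of 1.300, and with mICP 23 mmHg every classification flag is set:
the session shows intracranial hypertension, an elevated ratio (> 1.2)
and an elevated compliance index (> 19.3).

Cohort-level analysis on a simulated 72-patient cohort:

```r
coh <- simulate_cohort(cohort_sim_params(n_patients = 72, seed = 7))
rep <- run_pipeline(analysis_config(), cohort = coh)
rep
#> <nicpw_report>
#>   cohort: 72 patients
#>   mICP ~ P2/P1: r = 0.58 (p = 1.12e-07)
#>   P2/P1 -> IHT: AUROC 0.89 [0.77-1.00]
glance(rep$roc_iht)
#> # A tibble: 1 × 9
#>     auc ci_low ci_high     se n_pos n_neg level method degenerate
#>   <dbl>  <dbl>   <dbl>  <dbl> <int> <int> <dbl> <chr>  <lgl>
#> 1 0.887  0.774       1 0.0578    16    56  0.95 delong FALSE
```

At n = 72 the sampling noise is visible (the correlation drawn here is
0.58 against a calibration target of 0.49); at the calibration scale
(n = 2000) the simulated cohort reproduces its targets, which is what the
acceptance script checks.

A thin command-line wrapper with `simulate`, `analyze`, `roc` and
`report` subcommands is installed at `inst/scripts/nicpw-cli.R`.

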