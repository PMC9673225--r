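Package: nicpw
Title: Noninvasive Intracranial Pressure Waveform Morphology and
    Diagnostic Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pulsatile cranial-deformation recordings
    (noninvasive intracranial pressure waveforms, NICPW): cardiac-cycle
    segmentation, per-minute ensemble averaging with quality control,
    localisation of the P1 (percussion) and P2 (tidal) sub-peaks and the
    P2/P1 amplitude ratio, per-session mean ICP and the brain compliance
    index (BCI = mICP x P2/P1), plus the diagnostic-accuracy statistics
    used to relate these indices to intracranial hypertension and
    short-term outcome (Mann-Whitney AUROC, DeLong confidence intervals
    and paired AUROC comparison, operating-point performance with Wilson
    intervals, cohort summary tables, and AUC-based sample size). A
    seeded synthetic-data module generates three-peak ICP-like pulse
    recordings and patient cohorts with known ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
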