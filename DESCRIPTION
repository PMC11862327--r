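Package: hrvCrossover
Title: Heart Rate Variability Pipelines and Crossover Inference for
    Auricular Vagus Nerve Stimulation Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing continuous single-lead ECG from randomized
    within-subject (crossover) stimulation studies such as transcutaneous
    auricular vagus nerve stimulation (taVNS) versus sham. Provides ECG
    preprocessing (detrending, zero-phase Butterworth powerline and baseline
    removal, anti-aliased downsampling), Pan-Tompkins style R-peak detection,
    R-R interval artifact screening, time-domain (SDRR, RMSSD) and
    sliding-window Welch frequency-domain (HF, LF, LF/HF) heart rate
    variability, ECG-derived respiration rate, and a statistical layer for
    baseline-corrected condition contrasts: percentile bootstrap estimates,
    Benjamini-Hochberg adjustment, Cohen's dz, JZS Bayes factors, MANOVA with
    Pillai's trace, Fisher-z correlation comparisons, repeated-measures power
    analysis and blinding checks. A synthetic ECG/RR study generator with
    known ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
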