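Package: stressres
Title: Physiological Stress Scoring and Short-Term Resilience Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying short-term resilience to acute stress from
    multichannel physiological recordings. Derives per-phase autonomic features
    (heart rate, SDNN, LF/HF spectral power, peak-valley respiratory sinus
    arrhythmia, respiration rate, skin conductance level, electrodermal
    response rate, trapezius EMG RMS) from raw ECG, electrodermal, respiration
    and EMG channels sampled around a socioevaluative stressor and a series of
    task scenarios; computes a control-normalized physiological stress score;
    assigns rule-based resilience-trend labels (resistant, resilient, recovery,
    dysfunctional); screens baseline-profile outliers with a robust median/MAD
    rule; and fits a stochastic-gradient-descent hinge-loss linear classifier
    predicting the trend class from baseline salivary cortisol and state
    anxiety (STAI) scores. A seeded synthetic-cohort generator emulates
    complete sessions so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    e1071,
    mclust,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
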