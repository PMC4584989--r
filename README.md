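# stressres

Quantifying short-term resilience to acute stress from multichannel
physiological recordings.

In stress-training paradigms, participants wear ECG, electrodermal (EDA),
respiration and trapezius-EMG sensors through a seated baseline, a
socioevaluative stressor (a Trier Social Stress Test, TSST), and a series of
task scenarios. Whether a person barely reacts to the stressor, reacts and
returns to baseline, or reacts and stays elevated is an individual trait —
their short-term *resilience trend* — and practitioners want to predict it
from measurements that can be taken before any stressor is applied.
`stressres` implements that analysis end to end for researchers in
psychophysiology and human-performance training:

1. **Autonomic features per phase.** Raw 500 Hz channels are reduced, per
   annotated phase, to heart rate (from R-R intervals, with rates outside
   40–180 bpm excluded), SDNN, LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz)
   spectral power of the R-R tachogram and their ratio, peak-valley
   respiratory sinus arrhythmia, respiration rate, tonic skin conductance
   level (SCL), electrodermal response (EDR) rate per minute, and
   block-averaged EMG RMS.
2. **Physiological stress score.** For each experimental subject and phase,
   heart rate and SCL are divided by the control group's phase means and
   averaged:
   `score = ½·(HR / HR̄_control + SCL / SCL̄_control)`,
   so 1.0 is control-typical.
3. **Resilience-trend rules.** With ΔTSST and Δscenario the percent changes
   of the score from baseline: *resistant* if ΔTSST ≤ 5 %; otherwise
   *resilient* if Δscenario ≤ 5 %; otherwise *recovery* if the scenario
   score stays below the TSST score, and *dysfunctional* if it keeps rising.
4. **Baseline prediction.** A robust median/MAD screen flags discordant
   baseline profiles; the remaining (cortisol, STAI) pairs train a
   one-vs-rest hinge-loss linear classifier fitted by stochastic gradient
   descent (L2 penalty α = 1e-4, "optimal" learning-rate schedule), with
   logistic regression, perceptron, linear SVM, 1-NN, Gaussian naive Bayes
   and Gaussian-mixture models available as comparisons.
5. **Synthetic cohorts.** A seeded generator emits complete sessions — raw
   channels, phase manifests, baseline profiles, mission logs — with known
   per-subject phenotypes and latent targets, so every stage is testable
   without any recorded data.

## Worked example

```r
library(stressres)

# a 39-subject synthetic cohort (20 control / 19 experimental), reduced to
# per-phase features without keeping raw signals in memory
cfg <- cohort_config(seed = 1)
co  <- cohort_features(cfg)
res <- analyze_cohort(co$features, co$profiles)

res$counts
#>     resistant     resilient      recovery dysfunctional
#>             4            11             4             0

head(res$labels, 3)
#>   subject_id     label pct_change_tsst pct_change_scenarios
#> 1        S21 resilient           34.15                3.089
#> 2        S22 resilient           30.74                1.240
#> 3        S23 resilient           32.59                3.353

res$confusion
#> <confusion_summary> accuracy 66.7% (12/18)
#>            predicted
#> truth       recovery resilient resistant
#>   recovery         2         2         0
#>   resilient        0         8         3
#>   resistant        0         1         2
```

`pct_change_tsst` is the subject's stress-score rise at the stressor
relative to baseline (here ≈ +30 %, a clear reactor), and
`pct_change_scenarios` the residual elevation during the scenarios (≈ +1–3 %:
these subjects returned to baseline, hence *resilient*). The confusion
summary is resubstitution accuracy of the SGD classifier on the labeled
subjects that survive the outlier screen (here 18 of 19). Ground-truth
recovery for the same cohort:

```r
rep <- recover_cohort(cfg)
rep$recovery_rate   #> 1         (19/19 phenotypes recovered)
rep$hr_mae_bpm      #> 0.0535    (mean |measured - latent| heart rate, bpm)
```

A disk-based flow with the same semantics is available as
`run_generate()` / `run_analyze()` / `run_recover()`, and as a thin command
line in `inst/cli/stressres.R`:

```sh
Rscript inst/cli/stressres.R generate --out cohort/ --seed 1
Rscript inst/cli/stressres.R analyze  --sessions cohort/ --out cohort/out
Rscript inst/cli/stressres.R recover  --sessions cohort/
```

## Scope and formats

Sessions are plain text: one CSV per channel with a commented `key: value`
header (name, unit, sampling rate), TSV phase manifests / baseline profiles
/ mission logs. See `vignettes/stress-resilience-methods.Rmd` for the
model, parameter and design documentation, and the limits of what the
synthetic cohorts can establish about recorded data.
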