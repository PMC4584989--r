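---
title: "Methods: physiological stress scoring and resilience-trend classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological stress scoring and resilience-trend classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stressres)
```

`stressres` turns raw multichannel physiological recordings taken around an
acute stressor into a per-subject resilience-trend label, and asks whether
that label is predictable from two pre-stressor measurements: salivary
cortisol and self-reported state anxiety (STAI). This vignette documents the
models, every tunable that matters, the numerical choices, what the
synthetic cohorts emulate, and the limits of what the tests establish.

## The measurement model

A session is a set of synchronized channels — ECG (mV), electrodermal
activity (microsiemens), thoracic expansion (arbitrary units), trapezius EMG
(mV) — sampled at a common rate (500 Hz in the protocol this package
targets), plus a manifest of half-open phase intervals: a seated baseline of
at least 5 min, a socioevaluative stressor block (anticipation, speech,
mental arithmetic; 15 min), and five task scenarios. Sample `i` covers
`[i/fs, (i+1)/fs)`; half-open windows make phase slicing exact and
partition-safe.

### ECG: beats, heart rate, SDNN, spectral balance

R peaks are detected Pan-Tompkins style: a causal 5–15 Hz Butterworth
band-pass (order 2), squared derivative, 150 ms moving-window integration,
and thresholding at 0.3 times the 99th percentile of the integrated energy,
with a 240 ms refractory rule. Each candidate is then *refined to the raw
signal's maximum within ±75 ms*, which frees the pipeline from the filter's
group delay (this is why a causal filter suffices where one would otherwise
reach for a zero-phase pass) and pins clean-signal peaks to within one
sample. R-R intervals whose instantaneous rate falls outside 40–180 bpm are
masked invalid and excluded everywhere downstream; no other artifact
correction is attempted.

Heart rate over a window is `60 / mean(valid RR)`. SDNN is the standard
deviation of the valid intervals with the *population* (n) denominator —
a convention this package fixes and records in its configuration, since with
hundreds of beats per phase the n vs n−1 distinction is negligible but
reproducibility demands one choice. Windows shorter than 300 s are computed
but flagged, honoring the convention that SDNN is reported over >5 min.

Spectral balance: the valid R-R tachogram is linearly interpolated onto a
4 Hz grid, linearly detrended, and a Welch periodogram taken (Hann window,
64 s segments, 50 % overlap — segments long enough to resolve 0.04 Hz, short
enough to average several per phase). LF power integrates `[0.04, 0.15)` Hz,
HF `[0.15, 0.4]` Hz, by rectangular summation; the LF/HF ratio is undefined
(NA) when HF power is zero. Windows under 120 s of valid beats refuse to
estimate.

### Respiration and RSA

The respiration channel is block-averaged down to 4 Hz and band-passed to
0.05–1 Hz (zero-phase 4th-order Butterworth); inspiration onsets are rising
zero crossings, linearly interpolated between samples. The breathing rate is
`60 / mean(cycle length)`. Respiratory sinus arrhythmia uses the peak-valley
method on the same cycle series (one cycle definition for both outputs):
instantaneous heart rate is the stepwise `60/RR` assigned to each interval's
terminating beat, a cycle contributes `max − min` over the beats whose R peak
falls inside it, cycles with fewer than two beats are skipped, and the
subject value is the mean over at least three qualifying cycles. Stepwise
sampling of a sinusoidal modulation at 4–6 beats per breath recovers about
90–95 % of the true peak-to-peak amplitude — the recovery tests budget for
that bias.

### Electrodermal activity

All electrodermal content of interest lives below 1 Hz, so the channel is
block-averaged to 4 Hz before filtering; designing 0.05 Hz transfer-function
filters directly at 500 Hz is numerically fragile, and decimation makes the
pass both stable and cheap. The phasic component is the 0.05–1 Hz zero-phase
band-pass. An electrodermal response (EDR) is an upward crossing of a
0.05 microsiemens onset threshold; the event closes only when the signal
falls back below 0.049 (a 0.001 microsiemens Schmitt-trigger band, so
threshold ripple cannot double-count) and onsets are separated by a 1 s
refractory period. The EDR rate is the event count divided by the window
length in minutes — phase totals, not sliding minutes. Tonic skin
conductance level (SCL) is the mean of the sub-0.05 Hz low-pass of the raw
signal. A flat or saturated channel warns, reports rate 0 and still computes
SCL.

### EMG

Root mean square in non-overlapping 0.2 s blocks (100 samples at 500 Hz),
averaged over the window; trailing partial blocks are dropped.

## Stress score and trend rules

Only heart rate and SCL carried reliable stressor responsivity in this
paradigm, so the physiological stress score combines exactly those two,
each normalized by the *control group's* mean for the same phase:

score(subject, phase) = w · HR/HR̄_ctrl + (1 − w) · SCL/SCL̄_ctrl,  w = 0.5.

The equal weighting is a declared configuration default
(`stress_score.hr_weight`), not an estimate. Per-phase control means are the
default normalization (a control-typical subject then scores 1.0 in *every*
phase); a grand-mean variant is selectable. Subjects lacking SCL
(electrodermal sensor loss) keep their other features but are excluded from
trend analysis — exclusion, not imputation, because the score is undefined
without its electrodermal half.

With ΔTSST and Δscenario the percent changes of the score from baseline
(the scenario aggregate defaulting to the mean over available scenarios;
`last` and `max` are selectable):

* **resistant** — ΔTSST ≤ 5 %;
* **resilient** — ΔTSST > 5 % and Δscenario ≤ 5 %;
* **recovery** — both > 5 %, scenario score below the TSST score;
* **dysfunctional** — both > 5 % and the scenario level *exceeds* the TSST
  level (a response still rising; the class is defined for completeness and
  rarely observed).

The dysfunctional operationalization is the one genuinely open design
point: the class is described narratively as "kept rising", and comparing
the scenario aggregate against the TSST score is the direct reading of
that description. The rules depend only on score ratios, so labels are
invariant to positive rescaling; the 5 % threshold is `trend.threshold_pct`.

## Baseline profiles, outlier screen, classifier

The trend label is predicted from two baseline numbers: salivary cortisol
(micrograms/dl) and the STAI state total (20–80; item responses are summed
after reverse-keying anxiety-absent items, and this package's generator
emits pre-keyed items so no copyrighted item list is needed).

**Outlier screen.** A subject is flagged when either feature has robust
z-score `|x − median| / (1.4826·MAD) > 2.5`. The cut is calibrated to the
instrument: against cohorts matching the observed moments (cortisol
0.38 ± 0.28, STAI 30 ± 9), values of the kind the screen exists to catch
(cortisol ≈ 1.4, STAI ≈ 70) must be flagged essentially always, and at
n ≈ 20 the sample MAD of a right-skewed biomarker is noisy enough that a
cut of 3 misses such values in a few percent of cohorts. At 2.5 the screen
flags ~8 % of genuine subjects — deliberate: in a screening role, a flagged
subject is merely excluded from classifier *training*, never from reports.
A zero MAD (constant feature) falls back to the mean/SD rule.

**Classifier.** One-vs-rest linear scores over (cortisol, STAI), trained by
stochastic gradient descent on the hinge loss with L2 penalty α = 1e-4 and
the "optimal" schedule `η_t = 1/(α(t₀+t))`, `t₀ = 1/(η₀α)`, `η₀ = α^{-1/4}`
(= 10 at the default α, giving t₀ = 1000). Features are standardized to
train-set mean/SD before fitting (selectable off, for plots on raw axes);
up to 1000 epochs with shuffling under a recorded seed, stopping after five
epochs without a 1e-3 loss improvement. Evaluation is resubstitution by
design — with ~16 usable subjects there is no room for held-out
estimation, and the point of the worked analysis is the geometry of the
decision boundaries, not a generalization claim. A cross-validation path is
available but is an extension, not the protocol. Comparison methods
(logistic regression, perceptron, linear SVM, 1-NN, Gaussian naive Bayes,
Gaussian mixtures) share the evaluation contract; all but the perceptron
are delegated to standard implementations (`nnet`, `e1071`, `class`,
`mclust`).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every end-to-end claim is made. Defaults: 20 control + 19
experimental subjects; phenotype mixture 12/19 resilient, 3/19 resistant,
4/19 recovery (multinomial, seeded); phases of 300 s baseline, 900 s TSST,
5 × 600 s scenarios (per-subject scenario durations are not part of the
protocol record, so 600 s is a configurable package default); 500 Hz.

Each subject draws latent baselines (heart rate ~70 ± 6 bpm, SCL
~6 ± 1.5 microsiemens, respiration ~15 breaths/min, RSA amplitude
~6 bpm, EDR rate ~4/min) and, if experimental, applies the phenotype's
reactivity at the TSST and residual during scenarios (resistant 2 %/0 %,
resilient 30 %/1 %, recovery 30 %/15 %, dysfunctional 30 %/40 %; the same
percentages drive heart rate, SCL and EDR-rate targets). Controls stay
flat. A per-phase multiplicative jitter (SD 1.5 %) plus channel noise
(R-R jitter 20 ms, ECG noise 0.02 mV, EDA drift 0.08 microsiemens below
0.02 Hz, EDA noise 0.01 microsiemens, respiration noise 0.05) are all
scaled by one `noise_scale` master knob; 0 gives noiseless signals while
preserving subject-level heterogeneity. ECG is rendered as template QRS
complexes at the beat times; SCRs as bi-exponential kernels (1 s rise, 4 s
decay, 0.3 microsiemens — comfortably above the 0.05 detection threshold)
at renewal times with a 4 s dead time (gap lengths compensated so the
target rate is preserved); EMG as Gaussian noise at the target RMS; tonic
EDA ramps are Gaussian-smoothed (10 s) across phase boundaries so level
steps do not masquerade as phasic events.

Baseline biomarkers are phenotype-conditioned: cortisol is drawn from
truncated *log-normals* (salivary cortisol is right-skewed; a symmetric
mixture cannot reproduce the observed SD of 0.28 around a 0.38 mean while
keeping the robust scale small enough for a reliable MAD screen at n ≈ 20)
parameterized by per-phenotype mean/SD (resistant 0.54 ± 0.35, resilient
0.36 ± 0.24, recovery 0.24 ± 0.16), and STAI from truncated normals
(26 ± 7, 29.5 ± 7, 35 ± 8), integer-rounded and clipped to 20–80. The
mixture reproduces cohort moments of ≈ 0.38 ± 0.28 and ≈ 31 ± 7 while
encoding the gradient — resistant: high cortisol, low STAI; recovery: low
cortisol, high STAI; resilient between. The phenotype-conditional
distributions *overlap strongly* on purpose, mirroring how weakly separated
the real scatter is; a `separation` multiplier (means pushed apart, SDs
shrunk) produces the well-separated cohorts used for classifier-geometry
checks, where separation 3 is the convention for "strong". Final cortisol
is a drawn fraction (≈ 0.32) of baseline, reflecting the morning decline
rather than any HPA kinetics. Mission logs draw objective counts, shots
and durations with difficulty drifting across scenarios; only the score's
bounds and monotonicity are contractual.

Determinism: the master seed fixes the group plan, all per-subject
substreams, and therefore every emitted byte.

### What the synthetic tests do and do not show

Recovered-within-tolerance on synthetic cohorts demonstrates that the
pipeline's estimators are consistent with their own generative assumptions
at realistic SNR — it validates the *algorithms*, not the physiology. Real
recordings add ectopic beats and electrode artifacts (only the 40–180 bpm
rule is applied here), motion-contaminated EDA, inverted or low-amplitude
QRS morphologies, breathing irregular enough to break the single-sinusoid
RSA picture, and phase boundaries that are administratively, not
physiologically, sharp. Results on the synthetic cohort quantify the
pipeline's *best case*; they do not certify performance on recorded data.

## Problem sizes and numerical notes

End-to-end checks run the full study design (39 subjects, 7 phases, 500 Hz,
4200 s per subject) once at default noise and once noiseless; feature
extraction streams subject-by-subject so memory stays flat (~70 MB of
samples per subject transiently). Replicate-based checks (outlier screen,
classifier geometry) use 100 seeded replicates of the 19-subject
experimental group, profiles only. Degenerate inputs are contracts, not
accidents: flat ECG raises an error ("undetectable rhythm"), flat EDA warns
and reports rate 0, windows too short for an estimator return NA with a
log line, a single-class training set refuses to fit, and a zero control
mean refuses to normalize. Ties in the classifier's argmax resolve to the
first class in sorted order; the per-epoch shuffle seed is serialized with
the model so a refit from the text record is bit-reproducible.

## Known limitations

* ECG morphology analysis (QT/ST), SCR amplitude decomposition and
  artifact correction beyond the 40–180 bpm rule are out of scope.
* The EDR count convention (phase totals over phase minutes) is one of
  several defensible readings of a per-minute rate.
* Binary acquisition formats (EDF, vendor formats) are not read; sessions
  interchange as the documented text container. An EDF import would be a
  natural extension.
* Stress-decay/rise time constants — an attractive refinement of the
  recovery/resilient distinction — are deliberately not computed.
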