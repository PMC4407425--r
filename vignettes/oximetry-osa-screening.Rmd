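---
title: "Validating overnight oximetry as a screen for obstructive sleep apnea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating overnight oximetry as a screen for obstructive sleep apnea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odiscreen)
```

## The problem

Polysomnography (PSG) is the reference standard for diagnosing obstructive
sleep apnea (OSA), but it is expensive, labor-intensive and scarce. A finger
pulse oximeter records one of the PSG channels — arterial oxygen saturation
(SpO2) — cheaply and at home. The question this package operationalizes is:
how much of the PSG diagnosis can be recovered from that single 1-Hz SpO2
channel?

The quantity the oximeter supports is the **oxyhemoglobin desaturation
index** (ODI): the number of transient desaturation events per hour of
recording. An event is parameterized by a depth threshold *n* (percentage
points below a baseline), a baseline convention *b*, and a minimum duration
(3 s throughout). Two baselines are in common use:

* **A** — the all-night mean of the valid signal (one constant);
* **T** — the mean of the top 20% of valid SpO2 values in the minute
  preceding the scanned sample (a moving, adaptive baseline).

The four indices computed here are ODI2 and ODI3 (thresholds 2 and 3 with
baseline T), ODI4T, and ODI4A. The reference standard is the
apnea–hypopnea index (AHI) from full PSG, with the conventional severity
bands: normal < 5, mild 5–<15, moderate 15–<30, severe ≥ 30 events/h
(boundaries are left-closed, following the band convention used by the
reference cohort's tables rather than the looser "greater than" phrasing
that sometimes accompanies them).

Because the underlying patient recordings of the motivating validation
study were never deposited, the package is organized around a synthetic
cohort generator that reproduces the *statistical structure* of such a
cohort, so that every downstream stage — artifact handling, event
detection, index computation, cutoff and SVM classification, and the full
evaluation battery — is exercised end to end with a known ground truth.

## The synthetic cohort

`generate_cohort()` draws one record per patient. Severity-group sizes come
from largest-remainder rounding of the severity mix (11.7 / 20.6 / 21.4 /
46.3% by default, reproducing group sizes 72/127/132/285 at n = 616).
Per-group means and SDs of age, BMI, neck circumference, Epworth score,
sleep time, latency, arousal index and heart rate are taken from the
reference cohort's summary table (`default_group_params()`); draws are
truncated to physical ranges (age 20–85, ESS 0–24, BMI > 10, NC > 20).

AHI is not tabulated per group in the reference (it defines the grouping),
so the generator's AHI parameters are a design choice made once: normal
2.5 ± 1.8, mild 9.5 ± 2.8, moderate 21.5 ± 4.2, severe 56 ± 22, rejection
sampled into each group's band. The implied overall mean (~33 events/h) is
consistent with the reference overall AHI of about 34. Each patient draws
from the private seed `seed + i`, so cohorts are reproducible patient by
patient and a single global seed fixes everything.

## From AHI to a trace

`plant_events()` converts a target AHI and sleep time into an event
schedule: exactly `round(ahi * tst_hours)` events. Durations are uniform on
10–60 s; at high densities the ceiling shortens with the respiratory cycle
(`min(60, max(12, 0.6 * 3600/ahi))`), since severe patients cycle through
obstruction and recovery in well under a minute. Onsets are placed by
distributing the free recording time over the inter-event gaps as uniform
order statistics, which keeps onsets exchangeable while guaranteeing no
overlap and a minimum 10-s gap at any feasible density; infeasible rates
raise an error naming the approximate limit. Event depths follow a
two-component mixture: 85% "deep" (4.5–10 points, the clinically scoreable
class) and 15% shallow (1.5–4 points).

The waveform model in `synthesize_trace()` is deliberately simple — the
motivating analysis constrains event counts, depths and durations, not
morphology: linear descent over the first part of the event (slope capped
at 3 points/s), a plateau at the event depth, and exponential resaturation
with a 3-s time constant. The 10-s minimum gap together with the fast
recovery ensures consecutive events resaturate past even the shallow
2-point threshold, so distinct planted events remain distinct at every
index variant — the property that makes the empirical ordering
ODI2 ≥ ODI3 ≥ ODI4T hold on simulated recordings as it does on real ones.

The instrument model then applies the oximeter's beat-based exponential
averaging: a 4-beat window, doubling to 8 beats above 112 bpm and 16 beats
above 225 bpm. "Four-beat exponential averaging" underdetermines the
smoothing constant, so the convention adopted (and tested against its
closed form) is `alpha = 1 - exp(-beats_per_sample / window_beats)`: after
exactly one window of beats a step input is covered to `1 - exp(-1)`.
Gaussian measurement noise (SD 0.3 points) is added, and two artifact
classes are injected at configurable rates: downward single-sample motion
spikes of 5–15 points and probe-dropout readings below 50%.

What the generator does **not** emulate: REM/NREM architecture, positional
effects, periodic breathing oscillations, drift in the resting level, and
cardiorespiratory coupling. Passing tests therefore demonstrate that the
pipeline's machinery is correct and well-calibrated against this structure,
not that the specific published accuracies would be reproduced on real
recordings.

## Artifact elimination

`remove_artifacts()` implements the two automated rules: any reading below
50% is eliminated, and any change between consecutive 1-s samples
exceeding 4 points is eliminated (the later sample of the offending pair).
One boundary case needs a convention: when a sample's predecessor was
itself eliminated as a dropout, the slew comparison uses the most recent
retained value, so a single dropout costs one sample, not two. Samples are
masked, never deleted — the time axis is preserved and desaturation events
cannot span masked gaps. The operation is idempotent, and indices use the
artifact-free ("valid") time as their denominator by default; a
`denominator = "total"` switch exposes the alternative reading, since
summary descriptions of "total recording time" rarely say whether
artifact-deleted periods are excluded.

## The ODI engine

`detect_events()` works in two levels. A desaturation *episode* is a
maximal run of valid, baseline-defined samples strictly below the
baseline; episodes are broken by any invalid or baseline-undefined sample.
An episode counts for ODI-*n* when it contains at least 3 s of consecutive
samples at or below `baseline − n` (durations counted inclusively at 1 Hz:
three qualifying samples = 3 s; a strict "> 3 s" mode is available behind
`strict_gt`). Episode boundaries do not depend on the threshold, which
gives the definition its key structural property: event counts are exactly
monotone in the threshold (ODI4T ≤ ODI3 ≤ ODI2 on *every* trace, not just
in the mean). A detector that both starts and ends events at the threshold
crossing itself cannot have this property — measurement noise around
`baseline − n` fragments one deep episode into several threshold runs, and
partial recoveries merge others — and it also misreads the index
definition, which counts desaturation episodes *reaching* depth *n*, not
intervals spent below the line. The reported event extent is the episode's
first qualifying sub-threshold run, so every in-event sample satisfies the
threshold; the nadir is the episode minimum. The moving baseline returns `NA` until 12
valid samples precede the scan point (12 = the top-20% count of a full
60-sample window), so no event can begin in the first seconds of a
recording. The per-window mean of the top `ceil(0.2 m)` of `m` valid values
is computed in C++; the test suite checks it sample-for-sample against a
brute-force R implementation, and checks the detector against an
independent direct-scan oracle on hundreds of random traces.

"An *n*% decrease" is interpreted as an absolute drop of *n* saturation
points — the standard oximetry convention; a relative-percentage mode
exists behind the `relative` flag but is not the default.

## Classification and evaluation

Two binary screening tasks (severe: AHI ≥ 30; moderate-to-severe:
AHI ≥ 15) and the four-class problem are served by:

* **fixed cutoffs** (`cutoff_predict()`, inclusive at the boundary, with
  the reference cutoffs shipped via `osa_reference_tables("cutoffs")`),
* **ROC-optimal cutoffs** (`optimize_cutoff()`, maximizing Youden's
  J = sensitivity + specificity − 1 over all midpoints of adjacent unique
  values, ties resolved toward higher specificity; the criterion behind the
  published cutoffs is not recoverable, so J — the standard reading of
  "best discrimination" — is used and documented as swappable), and
* **kernel SVMs** (`svm_crossval()`): stratified ten-fold cross-validation,
  per-training-fold standardization, inner 3-fold grid search over
  C ∈ {0.1, 1, 10, 100} and γ ∈ {0.01, 0.1, 1} (degree fixed at 2 for the
  polynomial kernel), pooled out-of-fold predictions. Multiclass uses
  libsvm's one-vs-one voting over the six pairwise machines.

The evaluation battery mirrors a diagnostic-validation workup:
`confusion_metrics()` (accuracy, per-class sensitivity, misclassification
rates), `roc_auc()` (trapezoidal AUC, identical to Mann–Whitney
concordance with half credit for ties), `bland_altman()` (bias and
±1.96 SD limits of agreement, sample SD), `linear_calibrate()` (OLS
calibration of indices against AHI), `chi_square_test()` (Pearson, no
continuity correction — the reference gender-by-severity statistic 62.801
is reproduced only without correction), and `anova_from_summary()`
(one-way ANOVA reconstructed exactly from per-group n/mean/SD).

Post-hoc pairwise comparisons (`posthoc_orderings()`) default to
**Games–Howell** rather than a pooled-variance method. The reason is
visible in the reference summaries themselves: the severe group's ODI4A SD
(~25) is eighteen times the normal group's (~1.4). A pooled-MSE criterion
(Scheffé, Tukey) is dominated by the severe group's variance and cannot
separate the tight low-severity groups, even though they are ten SDs
apart on their own scale; Games–Howell uses per-pair variances with Welch
degrees of freedom and recovers the full published ordering
(1) < (2) < (3) < (4). Scheffé remains available via `method = "scheffe"`.

## Numerical and scale choices

* All randomness flows from one integer seed; derived seeds stay below
  2^31. Cohorts, traces, folds and SVM fits are byte-reproducible.
* The test suite runs cohorts of 100–160 patients and 200 random short
  traces per oracle check; the acceptance script simulates the full
  616-patient cohort. These sizes were chosen to exercise every code path
  at study-like class balance while keeping a complete run in minutes.
* Degenerate inputs are errors, not guesses: empty traces, all-invalid
  traces, single-class label sets, non-discriminative (constant) scores,
  zero contingency marginals, event densities that cannot be placed.

## Known limitations

* The synthetic morphology is piecewise-deterministic; spectral or
  nonlinear oximetry features would not transfer from it.
* Oximetry cannot score sleep: total sleep time, latency and arousal
  counts are consumed from the (simulated) PSG summary, never derived from
  the trace.
* Published accuracies/AUCs of the motivating cohort are point estimates
  on unavailable patient data; the package validates against the published
  summary tables exactly, and against simulation only for structural
  properties (ordering, agreement, parameter recovery).
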