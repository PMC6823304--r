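---
title: "Predicting tachycardia episodes from minute-level vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tachycardia episodes from minute-level vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tachyrisk)
```

## The problem

Tachycardia — a sustained elevation of heart rate — is one of the earliest
and most common vital-sign responses of critically ill patients to impending
cardiorespiratory instability. `tachyrisk` implements a complete pipeline
for predicting clinically meaningful tachycardia episodes from the
*numerics* tier of ICU monitoring data: vital signs sampled about once a
minute (heart rate, respiratory rate, SpO2, and systolic/diastolic/mean
arterial pressure), with all the irregular sampling, gaps, and artifacts
bedside monitors produce.

The pipeline has five stages, each exposed as ordinary functions:

1. **Episode detection** (`detect_episodes`). A tachycardia episode is
   operationally defined on the heart-rate channel: samples at or above a
   threshold (130 beats/min by default) are clustered whenever the
   threshold-free gap between them is at most 30 min; a cluster becomes an
   episode when it spans at least 5 min (first to last suprathreshold
   sample) and its *duty cycle* — the fraction of available heart-rate
   samples inside the span that are suprathreshold — is at least 10%.
2. **Cohort construction** (`case_windows`, `control_windows`). Case
   windows are the 30 min immediately before episode onsets; control
   windows are random 30-min stretches from never-tachycardic subjects
   (designs 1 and 2) or, in the within-patient design (group 3), windows
   placed 3 h before the subject's own first episode.
3. **Featurization** (`featurize_windows`). Each window becomes 42 named
   predictors: channel means; heart rate/respiratory rate/SpO2 standard
   deviations, regression slopes, total spectral power, autocorrelation
   sums, approximate and sample entropies, record densities; and
   last-5/last-10-minute means and slopes.
4. **Modeling** (`crossval_train`, `evaluate`, `feature_ranking`). L1
   (lasso) logistic regression and random forests under 10-fold
   cross-validation, scored strictly out of fold, with ROC/AUC evaluation
   and impurity- or coefficient-based feature rankings.
5. **Trajectories** (`rolling_risk`, `lift_trajectory`,
   `aggregate_trajectories`). Minute-updated risk over each record, and
   the patient-specific *lift* — risk divided by the subject's own
   baseline risk from an episode-free 3-h segment.

A seeded simulator (`simulate_cohort`) generates multichannel cohorts with
known episode times and a controllable pre-episode drift, so every stage is
testable end to end without access to clinical data.

## The episode definition and its edge cases

The detector works purely on observed samples. Two decisions deserve
emphasis because the operational definition leaves them open:

* **Gap rule.** A threshold-free gap of *exactly* 30 min still merges; only
  strictly longer gaps separate clusters.
* **Duty-cycle denominator.** We divide by the number of *available*
  heart-rate samples inside the episode span, not by elapsed minutes.
  With complete minute-level data the two coincide; under missingness the
  sample-count denominator does not silently dilute density. This is a
  deliberate choice and the main point where reimplementations may differ.
* **Boundaries.** Episode start and end are the first and last
  suprathreshold samples of the cluster, so a single suprathreshold sample
  has zero duration and can never satisfy the 5-min minimum.

Comparisons use `>=` at the threshold: a 130.0 beats/min sample is
suprathreshold.

## Window features: parameters and conventions

All features are computed within a half-open window `[t_start, t_end)`, so
a case window ending at an episode onset never contains the onset sample
itself.

* **Means, SDs, slopes** use the raw irregular samples; slopes are
  ordinary least squares against time in minutes.
* **Spectral power, autocorrelation, entropies** operate on a uniform
  1-min grid obtained by cubic-spline interpolation, *provided at least
  20% of the expected samples are present*; below that floor the feature
  is missing. The spline never extrapolates: boundary grid points are
  anchored to the nearest observed value. Spectral power is the sum of
  squared unnormalized DFT amplitudes over frequencies 0 to 1/120 Hz
  inclusive — the DC bin is kept, which makes the feature strongly
  correlated with the window mean, a property inherited by design. For a
  30-min window at 1/min, 1/120 Hz is the Nyquist frequency, so the band
  covers the full one-sided spectrum.
* **Autocorrelation** is summed over lags 1–10 min. The lag scheme is a
  package choice; the feature is missing for zero-variance windows.
* **Entropies** use the literature defaults m = 2 and r = 0.2 times the
  window-grid SD. ApEn includes self-matches (so a constant window gives
  exactly 0); SampEn excludes them and is `-log(A/B)`, undefined (missing)
  when no template pairs match at either length. On short noisy windows
  SampEn is *frequently* undefined — that is correct behavior, and the
  missingness is handled downstream. Note ApEn is not monotone in r: at
  small tolerances match sparsity biases the statistic, so tests of the
  matching machinery assert monotonicity of the match *counts*, which is a
  theorem, rather than of ApEn itself.
* **Missingness** is never imputed at featurization time; a
  `FeatureVector` carries explicit `NA`s. Median imputation happens inside
  cross-validation, per fold, using training-fold medians only.

## Modeling choices

Folds are stratified by class and grouped by subject (no subject on both
sides of any fold); window-level stratification is available via
`pipeline_config(group_folds = FALSE)` for strict comparability with
designs that do not state grouping. Every window's score comes from the
single fold model that never trained on it; new data (trajectories) are
scored by the mean of the fold models.

The lasso penalty is selected by nested, class-stratified 5-fold
cross-validation inside each training fold; when a training fold is too
small for that (fewer than 4 windows in a class), the penalty falls back
deterministically to the midpoint of the glmnet regularization path. The
forest uses 500 trees, `sqrt(p)` candidate features per split, minimum
node size 1, and no depth cap. All randomness — fold assignment, inner CV
folds, tree growing — derives from `pipeline_config(rng_seed = )`, making
fold splits and scores bit-reproducible.

## Trajectories and the lift score

`rolling_risk` scores the preceding 30-min window at every minute from
minute 30 onward; minutes whose window fails the 20% coverage rule are
missing. The *lift* normalizes a subject's pre-onset risk by their own
baseline: the baseline is the mean risk over the 3-h segment ending
`baseline_hours` (default 3 h) before first-episode onset, and lift(t) =
risk(t)/baseline over the final 3 h before onset. Subjects lacking the
required episode-free history are excluded; a numerically zero baseline
(below 1e-6) leaves the lift undefined rather than exploding. Group
summaries (`aggregate_trajectories`) use per-minute means with a
normal-approximation 95% band; the band construction is a package choice.

## What the simulator emulates — and what it does not

Each simulated channel is a subject-specific baseline (population mean plus
between-subject offset) with stationary AR(1) noise on the 1-min grid.
Case subjects get a linear heart-rate ramp beginning 90 min before a
scheduled onset (0.3 beats/min per min by default), a coupled respiratory
rise and SpO2 decline, then an episode period in which each minute is
suprathreshold with probability `episode_duty` (0.35 by default, the mean
duty cycle reported for operationally defined episodes; the onset minute is
always suprathreshold and at least 10% of episode minutes are forced).
Samples are deleted independently at 10%, and control records carry
single-sample artifact spikes (HR 180–250) at 0.2/h.

Three guarantees make ground truth exact rather than approximate: outside
scheduled episodes heart rate is clipped just below the threshold, so no
stochastic crossing can create an unscheduled episode; artifact spikes are
thinned to lie further apart than the merge gap, so they can never
cluster into a duration- and duty-satisfying false episode; and every
subject is generated from a seed derived deterministically from the cohort
seed.

The defaults describe a stable adult ICU population (HR 85 ± 8 between
subjects, minute-to-minute SD 4 with lag-1 autocorrelation 0.85; RR 18;
SpO2 97; ABP 120/62, MAP 82). The AR(1)+ramp construction is the minimal
generator that gives every feature family non-trivial values — variance
for the SDs, memory for autocorrelation and the entropies, a ramp for the
slopes, deletions for the densities. It is *not* a physiological model:
there are no circadian rhythms, interventions, rhythm changes, or
measurement-mode switches, and real pre-tachycardia dynamics are neither
linear nor universally present. Passing tests on this generator
demonstrate the pipeline's correctness and its ability to recover a
planted signal; they say nothing about clinical performance, which in the
motivating work was established on an archived ICU database and is not
reproducible without it.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at sizes a laptop handles
comfortably, chosen as the package's own verification scale: detector
oracle equivalence on 200 random series up to 5,000 samples; entropy
oracles on 50 series up to 200 samples; model sanity on a
20-case/20-control default cohort per seed, with the lag ladder averaged
over 20 seeded cohorts; and lift behavior on 20 seeded 5+5 cohorts.
Statistical assertions (chance-level AUC under permutation, lift above 1
before onsets, trajectory flatness on stationary records) are made at
fixed seeds with margins well beyond their sampling noise.

## Known limitations

* The duty-cycle denominator and episode boundary conventions are choices
  where the operational definition is silent; both are documented above.
* The artifact screen for control windows (values outside 20–300
  beats/min or single-step jumps above 60 beats/min) is a stated stand-in
  for the unspecified screening that produced artifact-free control sets
  in the motivating study.
* Entropy and spectral features at 1/min granularity carry limited
  information (30 grid points per window); they are computed exactly as
  defined, but their discriminative value grows with sampling rate.
* `evaluate` reports pooled out-of-fold performance; per-fold variance is
  available from the bundle but not summarized.

## A minimal run

```{r example, eval = FALSE}
co  <- simulate_cohort(sim_config(n_case_subjects = 10,
                                  n_control_subjects = 10, rng_seed = 1))
cfg <- pipeline_config(n_folds = 5, rng_seed = 1)
eps <- detect_episodes_cohort(co$records, cfg)
d   <- lagged_dataset(co$records, eps, lag_min = 0, cfg = cfg)
fit <- crossval_train(d$features, d$labels, "random_forest", cfg)
evaluate(fit)$auc
feature_ranking(fit, top_k = 15)
lift_trajectory(co$records[["C001"]], fit, eps, cfg)
```
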