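# tachyrisk

Predicting tachycardia episodes from minute-level ICU vital signs.

Tachycardia is an early, sensitive (if unspecific) marker of impending
cardiorespiratory instability in critically ill patients. `tachyrisk` is an
R implementation of a complete prediction pipeline over the *numerics* tier
of ICU monitoring — heart rate (HR), respiratory rate (RR), SpO2, and
arterial pressures sampled about once per minute — for researchers working
with bedside-monitor trend data (e.g. the PhysioNet MIMIC numerics records)
or with any long-format `subject,time_s,channel,value` CSV.

## What it computes

**Episode detection.** A tachycardia episode is a cluster of HR samples
`>= 130` beats/min, merged across threshold-free gaps `<= 30` min, retained
when it lasts `>= 5` min and has duty cycle `>= 10%` — duty cycle being the
fraction of available HR samples inside the episode span that are
suprathreshold.

**Case/control windows.** 30-min windows ending at (or a configurable lag
before) episode onsets, against random windows from never-tachycardic
subjects (groups 1–2) or within-patient windows 3 h before the first
episode (group 3, "internal controls").

**42 window features.** Per channel as applicable: means, SDs, OLS slopes,
total spectral power (cubic-spline gap-filling to the 1-min grid, sum of
squared DFT amplitudes over 0–1/120 Hz including DC, requiring >= 20%
coverage), autocorrelation sums (lags 1–10 min), approximate and sample
entropy (m = 2, r = 0.2 sd), record density, and last-5/last-10-min means
and slopes.

**Risk models.** Lasso logistic regression (`glmnet`, penalty chosen by
nested CV) and random forests (`ranger`, 500 trees) under subject-grouped,
class-stratified 10-fold cross-validation; pooled out-of-fold scores in
[0, 1], ROC/AUC by trapezoid, and feature rankings.

**Trajectories and lift.** Minute-updated risk over each record
(`rolling_risk`), and the patient-specific lift score: risk divided by the
subject's own mean baseline risk over an episode-free 3-h segment
(`lift_trajectory`), with group aggregation (`aggregate_trajectories`).

A seeded simulator (`simulate_cohort`) produces multichannel cohorts with
ground-truth episode times, AR(1) channel noise, pre-episode HR drift with
RR/SpO2 coupling, missingness and artifact spikes, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(tachyrisk)

co  <- simulate_cohort(sim_config(n_case_subjects = 10,
                                  n_control_subjects = 10, rng_seed = 1))
cfg <- pipeline_config(n_folds = 5, rng_seed = 1)

eps <- detect_episodes_cohort(co$records, cfg)
head(eps, 3)
#>   subject start_s end_s duration_s n_samples n_supra      duty
#> 1    C001   27120 28500       1380        20       9 0.4500000
#> 2    C002   28740 30180       1440        22      10 0.4545455
#> 3    C003   33000 34020       1020        16      11 0.6875000

d   <- lagged_dataset(co$records, eps, lag_min = 0, cfg = cfg)
fit <- crossval_train(d$features, d$labels, "random_forest", cfg)
evaluate(fit)$auc
#> [1] 0.985
feature_ranking(fit, top_k = 3)
#>              feature importance
#> 1  last_5min_mean_hr  0.8133999
#> 2             reg_hr  0.7608517
#> 3 last_10min_mean_hr  0.7584029

lt <- lift_trajectory(co$records[["C001"]], fit, eps, cfg)
mean(lt$lift[lt$minute > -30])   # mean lift in the last 30 min before onset
#> [1] 1.471975
```

Detected episode starts sit on the scheduled onsets of the simulator's
truth table (the duty cycles reflect the generator's ~35–45% suprathreshold
density); the planted pre-episode drift makes the lag-0 cohort almost
perfectly separable (pooled out-of-fold AUC 0.985), heart-rate level and
slope features dominate the ranking, and the lift rises above 1 approaching
the onset — this subject's risk in the final half hour is ~1.5x their own
stable baseline.

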