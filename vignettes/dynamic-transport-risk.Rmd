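---
title: "Methods: dynamic mortality risk from transport vital-sign streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic mortality risk from transport vital-sign streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Critically ill children moved between hospitals by specialist retrieval
teams die more often than other paediatric intensive-care admissions.
The only risk quantification routinely available during such transports
is a single-time-point severity score (PIM3-style), recorded when the
team first reaches the bedside; it cannot see deterioration that unfolds
*during* the journey. `vitalrisk` implements a dynamic alternative: it
converts the continuously monitored vital signs (HR, SBP, DBP, MBP, RR,
SpO2, temperature) into a 30-day mortality risk that is re-estimated
every 10 minutes and explained feature-by-feature, so a transport team
can see both the current risk and *why* it changed.

## Pipeline model

The pipeline treats one transport episode as a pair (static EHR record,
multichannel time series) and proceeds in fixed stages:

1. **Cleaning.** Monitor readings outside closed clinical plausibility
   intervals (HR `[0,300]` bpm, SBP `[0,270]`, DBP `[0,250]`, MBP
   `[0,250]` mmHg, RR `[0,180]` /min, SpO2 `[0,100]` %, temperature
   `[20,45]` °C) are converted to missing. They are never clipped:
   clipping a 400 bpm artifact to 300 bpm would fabricate physiology,
   whereas a gap is honestly recoverable by imputation.
2. **Imputation.** Interior gaps are linearly interpolated in time;
   leading/trailing gaps take the nearest observed value. The policy is
   per-channel and deterministic, uses no information from other
   channels (no cross-channel leakage), and preserves every observed
   value. A channel with zero observations in an episode cannot be
   imputed; it is excluded with a logged reason and any window needing
   it is dropped.
3. **Age-standardisation.** Paediatric vital signs vary enormously with
   age (a newborn heart rate of 140 bpm is normal; an adolescent's is
   not). Each channel is mapped to a Z-score,
   `z = (value − ref_mean(age group, channel)) / ref_sd(age group, channel)`,
   so model features measure deviation from the age-expected norm. The
   reference table ships as an editable YAML config with plausible
   placeholder values (e.g. newborn HR 140 ± 20 bpm, SpO2 98 ± 1.5 %);
   a deployment should substitute its preferred published references.
   The stage order clean → impute → standardise is fixed; since the
   Z-map is affine and strictly monotone per channel, standardising
   commutes exactly with the cleaning bounds and with linear
   interpolation, so the alternative order (standardise before impute)
   would produce identical Z-series — we keep imputation in raw units
   because its edge-fill semantics are easier to audit there.
4. **Windowing and features.** Streams are cut into 10-minute windows.
   Because deaths are rare (~6%), deceased patients' streams are
   oversampled with overlapping windows advancing by 50 grid points,
   while survivors contribute consecutive non-overlapping windows; at
   the default 1 Hz grid this makes the two sample classes
   approximately equal in number. Each window yields 13 statistics per
   channel — mean, median, SD, min, max, range, IQR, skewness, excess
   kurtosis, Shannon entropy of 16 equal-width bins over Z ∈ [−5, 5],
   sample entropy (m = 2, r = 0.2·SD), total periodogram power, and the
   least-squares slope per second — concatenated with 21 encoded static
   variables (age, age-group indicators, weight, gender, diagnosis-group
   indicators, ventilation, vasoactive-agent code, inhaled NO, PIM3
   risk, critical-incident code, transport time) into a 112-feature
   vector labelled with the patient's 30-day outcome.
5. **Modelling and fusion.** Classifiers (random forest, penalised
   logistic regression, and two gradient-boosting variants — depth-wise,
   and histogram/leaf-wise in the LightGBM style via xgboost's
   loss-guide mode) are trained at the window level. Hyperparameters
   are chosen by random search scored with mean AUROC over 5
   cross-validation folds grouped by patient: a patient's windows never
   straddle a fold boundary, and the 90/10 train/holdout split is
   likewise by patient and outcome-stratified, so no information leaks
   between sides. A patient's risk is the arithmetic mean of their
   window probabilities; the mean is order-independent, bounded by the
   window probabilities, and robust to the varying number of windows
   per patient. An optional stacking layer fits a logistic meta-model
   on out-of-fold base-model predictions.
6. **Evaluation.** AUROC is computed by the Mann–Whitney rank statistic
   with ties counted half; MCC, PPV, NPV, recall and F1 come from the
   confusion matrix at an operating threshold; average precision is the
   stepwise area under the precision–recall curve. The operating
   threshold is nowhere prescribed by the problem, so the default is
   the Youden-J maximiser on the evaluated scores, and the report
   always records the threshold it used. Confidence intervals are
   percentile bootstrap over *patients* (not windows), because the
   patient is the unit of inference; single-class resamples are redrawn
   and counted.
7. **Explanation.** Each window's predicted probability is decomposed
   into per-feature Shapley contributions. Exact enumeration over all
   feature coalitions (background-averaged) is available up to 12
   features; beyond that a seeded permutation-sampling estimator is
   used. Both modes satisfy local accuracy — base value plus all
   contributions equals the prediction — exactly: in sampled mode each
   permutation telescopes from a background prediction to the instance
   prediction, so the identity holds with the base defined as the mean
   prediction over the drawn background rows. Attributions are reported
   in probability space, matching what a bedside display plots. A
   *transition moment* is any window where a feature's contribution
   flips from ≤ 0 (favouring survival) to > 0 (favouring
   non-survival); an optional dead-zone suppresses flips that do not
   clear a band around zero (default 0, the strict sign-flip reading).

## The synthetic cohort generator

Real transport-monitoring data are restricted, so the package includes
a first-class generator whose defaults encode the conditions the
pipeline assumes:

* 30-day mortality 6%, applied deterministically
  (`round(n × rate)` deaths) so small-cohort tests are exact; 27% of
  deaths occur within 48 h.
* Monitoring duration LogNormal(log 67, 0.65) minutes, floored at
  10 min — median 67 min, IQR ≈ 41–104 min.
* Age-group mix 38/21/18/14/10% (newborn → adolescent), diagnosis and
  intervention frequencies typical of a retrieval cohort, transport
  time LogNormal(log 206, 0.334) minutes, critical incidents in 14.9%.
* Per-channel missingness at archival rates (2.9–12.5%) plus a small
  out-of-range outlier rate.
* Trajectories: each channel follows a discretised Ornstein–Uhlenbeck
  process in Z space (mean-reversion timescale 300 s, stationary SD
  0.6 Z) around a patient-specific offset (SD 0.4 Z). Survivors are
  stationary; non-survivors deteriorate linearly, with an
  episode-averaged displacement of −1.5 Z in SpO2 and −1.0 Z in SBP
  relative to survivors (the drift starts at 0 and reaches twice the
  configured effect by handover, so the trajectory is progressively
  deteriorating while its mean shift equals the configured value).
  This is the simplest process that gives stationarity for survivors
  and progressive deterioration for non-survivors.
* PIM3 risk is drawn from outcome-conditioned Beta distributions —
  Beta(2, 50) for survivors (median ≈ 3.3%), Beta(1.5, 18) for
  non-survivors — calibrated once by Monte Carlo so that PIM3 alone has
  moderate patient-level discrimination (AUROC ≈ 0.72 on large
  cohorts), i.e. the baseline is informative but clearly weaker than a
  model that also sees the dynamics.

**Sampling interval.** The raw archive frequency of transport monitors
is not standardised. The generator's default is 1 Hz: with 10-minute
(600-point) windows and the 50-point minority step, 1 Hz is the
interval at which the overlapping/non-overlapping windowing scheme
actually balances the two sample classes at 6% mortality — at, say, one
point per 5 s the minority class would be under-sampled roughly
six-fold. The interval remains a config field for other monitor
set-ups.

**What the generator does not emulate.** Stabilisation phases at the
referral hospital, bursty telemetry dropouts (missingness is
pointwise-independent), cross-channel physiological coupling,
medication effects, repeated transports of the same child, and any
real-data relationship between the static variables and the vital-sign
dynamics beyond the outcome-conditioned drift. Tests passing on this
cohort therefore demonstrate that the pipeline recovers a planted
dynamic signal under realistic noise, missingness and class imbalance —
not that the quoted discrimination would be attained on hospital data.

## Numerical conventions

* Constant windows: SD, range, IQR, slope, skewness, kurtosis, both
  entropies and spectral power are all defined as 0 (logged, not an
  error).
* Sample entropy uses Chebyshev distance, template length m = 2,
  tolerance r = 0.2·SD, self-matches excluded; degenerate counts give 0.
* Total periodogram power is computed from the FFT of the mean-removed
  window and by Parseval equals the population variance — the tests
  exploit this identity as an independent check.
* Windows are half-open `[start, start + w)` on the resampled grid; the
  minority step is counted in grid points, so its wall-clock meaning
  scales with the sampling interval.
* The Shapley background set is a seeded subsample (default 100 rows)
  of training samples; a risk trace reuses the *same* seed for every
  window (common random numbers), so window-to-window attribution
  changes reflect the data rather than estimator noise — without this,
  near-zero contributions would flip sign spuriously between windows
  and flood the transition detector.
* Model backends are seeded and single-threaded; identical inputs give
  identical models, features and attributions.

## Problem sizes used in the shipped checks

The end-to-end signal-recovery check uses cohorts of 600 patients at
1 Hz (about 20 M vital-sign points per cohort) over five generator
seeds, with the fixed reference random forest (300 trees, mtry 30%,
minimum node size 5) fitted directly; bootstrap calibration uses 200
trials of n = 300 with 1000 resamples each; Shapley axioms are verified
exactly on ≤ 12-feature models and by convergence of the sampled
estimator. These sizes were chosen as the smallest at which the
patient-level comparisons are stable.

## Known limitations

* The 13-statistic set and the static codebook are fixed, documented
  choices; a deployment validating against its own registry may need
  different encodings (e.g. one-hot vasoactive agents).
* No probability calibration (Platt/isotonic) is applied; fused risks
  are comparable within a model but are not calibrated frequencies.
* The explanation module attributes the model's prediction, not the
  patient's physiology: a sign flip is a statement about the model.
* Exact Shapley is exponential in features; full 112-feature vectors
  are always attributed by the sampled estimator, whose per-feature
  Monte-Carlo standard errors are reported alongside.
* The evaluation module deliberately omits DeLong tests, calibration
  plots and decision-curve analysis.
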