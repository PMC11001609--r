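---
title: "Concept-drift-adaptive seizure prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-drift-adaptive seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftseize)
```

## The problem

Roughly a third of people with epilepsy do not achieve seizure control with
medication. For them, a warning a few minutes before a seizure — enough time
to sit down, call for help, or take rescue medication — would change daily
life. EEG-based seizure prediction tries to detect the *preictal* state, a
window of altered brain dynamics before seizure onset. Two timing parameters
frame the task:

* **SOP** (seizure occurrence period): the window during which the seizure
  is expected after a warning; it equals the labelled preictal duration.
  Patient-specific, searched over 10–50 min in 5-min steps.
* **SPH** (seizure prediction horizon): the 10-min gap between the alarm and
  the start of the SOP, giving the patient time to act.

The difficulty this package addresses specifically is **concept drift**:
EEG statistics change over hours and days (medication tapering, sleep
deprivation, circadian state), so a classifier trained once degrades. The
package implements a patient-specific pipeline that retrains after every
seizure and, on top of that, adapts *within* the training data using three
strategies, compared against a non-adaptive control.

## The pipeline

For each patient with at least four lead seizures (seizures at least 4.5 h
apart):

1. **Signals.** Continuous multichannel scalp EEG (19 channels, 256 Hz in
   the targeted recordings) is band-pass filtered (0.5–100 Hz, zero phase)
   with 50/100 Hz notches, then cut into 5-s non-overlapping epochs.
2. **Features.** Per epoch and channel, 59 univariate linear features:
   8 relative band powers (delta, theta, alpha, beta, four gamma sub-bands),
   their 28 pairwise ratios, spectral edge frequency/power, alpha peak,
   total power, mean frequency, db4 wavelet detail energies D1–D5, the four
   statistical moments, the three Hjorth parameters, and the decorrelation
   time.
3. **Labelling.** Epochs in `[onset − (SPH+SOP), onset − SPH)` are preictal;
   epochs from the end of the previous postictal exclusion up to the
   preictal start are interictal. SPH, ictal and postictal epochs are
   excluded from training.
4. **Training.** Add-One-Forget-One: each new seizure becomes the test
   target, with the three immediately preceding seizures as training set.
   Hyperparameters (SVM cost, number of features, SOP) are chosen by
   leave-one-seizure-out grid search maximising the geometric mean of
   sample sensitivity and specificity. Features are z-scored with
   train-fitted parameters; selection is a one-way ANOVA-F filter.
5. **Drift adaptation.** The final model is trained by one of:
   * **Control** — plain linear SVM on all three seizures, classes balanced
     by systematic random undersampling.
   * **Backwards-Landmark Window (BLW)** — candidate windows grow backwards
     from the most recent training seizure in 1-h steps; each candidate's
     SVM gets a leave-one-out (xi-alpha) error estimate; the minimising
     window wins, with a 12-step early-stop patience.
   * **Seizure-batch Regression (SbR)** — a ridge logistic regression per
     chronological combination of the training seizures; each weight vector
     is compared by angle against a reference fitted on the most recent
     seizure only; the smallest-angle combination trains the final SVM.
   * **Dynamic Weighted Ensemble (DWE)** — one SVM per 1-h interictal
     segment (sharing the preictal pool), weighted by accuracy on the two
     hours before the last training seizure, combined by weighted voting.

   The adaptive variants balance classes with inverse-frequency class
   weights instead of undersampling.
6. **Alarms.** Test-epoch classifications are smoothed by the Firing Power
   — a causal moving average over one SOP of epochs (SOP minutes × 12 for
   5-s epochs) — and an alarm fires on an upward crossing of 0.5, followed
   by an SOP-long refractory period. The threshold is deliberately fixed at
   half scale rather than tuned.
7. **Evaluation.** Seizure sensitivity SS (predicted/tested seizures) and
   FPR/h (false alarms per interictal hour, refractory time excluded from
   the denominator), plus surrogate validation: seizure onsets are redrawn
   uniformly within their interictal intervals 30 times, surrogate
   sensitivities are scored against the unchanged alarms, and a one-sample
   t-test (α = 0.05) asks whether the achieved sensitivity exceeds the
   surrogate distribution.

## Key tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sop_grid` | 10–50 min, step 5 | candidate preictal durations |
| `sph` | 10 min | warning horizon |
| `postictal_exclusion` | 30 min | data discarded after each seizure |
| `independence_gap` | 4.5 h | lead-seizure spacing |
| `cost_grid` | 2^-10 … 2^2 | SVM costs searched |
| `n_features_grid` | 10, 20, 30, 40 | filter-selected feature counts |
| `fp_threshold` | 0.5 | Firing Power alarm threshold (fixed) |
| `step_hours` (BLW) | 1 h | window enlargement step |
| `early_stop` (BLW) | 12 steps | patience of the window search |
| `angle_tol` (SbR) | 15° | near-tie band for subset selection |
| `concept window` (DWE) | 2 h | recent period defining the current concept |
| `surrogate_runs` | 30 | surrogate repetitions |

The postictal exclusion is not prescribed by the underlying study design;
30 min avoids postictal contamination of the interictal class without
discarding excessive data, and it is configurable.

## Numerical and design choices

**Feature registry composition.** The enumerable battery (8 band powers +
28 ratios + alpha peak + total power + mean frequency + 5 wavelet energies
+ 4 moments + 3 Hjorth + decorrelation time + a spectral-edge pair) counts
54. To reach the canonical 59 the registry carries seven spectral-edge
entries — edge frequency and power at the 50th, 75th and 90th percentiles
plus the 95th-percentile edge frequency — replacing the single pair. The
registry is data-driven, so any alternative composition can be configured;
tests pin the default at exactly 59 uniquely named entries.

**PSD estimator.** A Hann-tapered periodogram over the whole 5-s epoch
(one Welch segment): 0.2 Hz resolution, Parseval-consistent within 5%.
Band-ratio division is guarded by `eps = 1e-12`; kurtosis is non-excess;
the wavelet transform is periodized (so detail + approximation energies
equal signal energy); spectral edges use the 0.5–100 Hz range with a 1e-6
relative guard so an exactly-half power split resolves to the lower line.
The decorrelation criterion is the first crossing of 1/e.

**Standardisation.** Sample standard deviation (`n−1`); zero-variance
features map to 0 and are flagged, never NaN.

**xi-alpha leave-one-out estimate.** The BLW window score is the fraction
of training points with `alpha_i·R² + xi_i ≥ 1` (`R²` = maximum kernel
self-similarity). The conservative textbook bound carries a factor 2 on
the alpha term, but that form can never return 0 — for a hard-margin
support vector, `2·alpha·R² ≥ R²/γ² ≥ 1` always — which would make the
estimate useless for discriminating clean windows. The implemented form is
0 on wide-margin separable data and upper-bounds the exact leave-one-out
error in practice at the default cost; at very small costs
(strong underfitting) it can occasionally undershoot by one point. An
exact mode (`n` retrainings) is available as an oracle. The window search
evaluates the estimate on the whole candidate window.

**SbR candidate space and tie handling.** "Every chronological
combination" is read as all non-empty subsets of the three training
seizures, excluding the reference singleton (whose angle to itself is
identically zero and carries no information). Because angles are
continuous, exact ties never occur; angles within `angle_tol` of the
minimum are treated as tied and the largest, then most recent, subset
wins. The default of 15° was calibrated once against the generator's two
regimes: same-distribution subsets disagree by under ~5° at these batch
sizes, while drift-contaminated subsets disagree by well over 20°. The
reference regression excludes the intercept from the angle.

**DWE composition.** Each base model trains on its 1-h interictal segment
plus the shared pool of all training preictal rows (guaranteeing two
classes); segments with fewer than 12 epochs are skipped. A weighted vote
of exactly 0.5 predicts preictal, favouring sensitivity in line with the
Firing Power threshold convention.

**Alarm semantics.** "Threshold surpassed" is an upward crossing; epochs
inside a refractory interval re-arm the detector, so a trace pinned at 1.0
raises exactly one alarm per refractory period. A true alarm is one whose
onset falls in `(t + SPH, t + SPH + SOP]`. Refractory time following false
alarms is removed from the FPR/h denominator. The Firing Power history is
zero-padded, damping the warm-up.

**Surrogate onsets** keep at least SOP+SPH from the interval start so the
surrogate preictal window fits inside the interictal interval, and each
onset stays within its own seizure's interval (preserving the seizure
distribution across time). When all surrogate sensitivities are identical
the t statistic is undefined; the verdict then falls back to the strict
comparison.

## The synthetic generator

Real long-term annotated scalp EEG is access-restricted, so the package
ships a two-tier generator that defines the study conditions for all tests:

* **Raw-signal tier** (`generate_recording`): AR(1)-coloured background
  (approximately 1/f) per channel; preictal windows add band-limited
  oscillations in configurable bands (alpha by default) at an amplitude set
  by `effect_size`; ictal segments carry a high-amplitude 4 Hz rhythm. Used
  to exercise the full signal path (filtering, segmentation, feature
  extraction).
* **Feature tier** (`generate_feature_stream`): draws 59-dimensional
  feature rows directly from interictal/preictal Gaussians whose signature
  dimensions (the effect bands' relative powers and their ratios) are
  shifted by `effect_size` pooled SDs. This keeps pipeline-level tests fast.

Defaults mirror the targeted cohort: 19 channels, 256 Hz, at least four
lead seizures, 4.5-h gaps, 10-min SPH. Tests use compressed timelines
(1–3 h gaps, one channel) purely to bound runtime; the geometry of
labelling is unchanged.

**Drift model.** An abrupt concept inversion swaps the two class
distributions in place: the pre-drift background on the signature features
is offset by `baseline_shift` (default: the effect size) and the preictal
shift flips sign. This mirrors a change of hidden context — medication or
vigilance shifts alter background EEG statistics, not only the preictal
signature — and it is the regime in which adaptation genuinely matters: a
drift that merely relocates one class lets a static SVM concentrate its
errors on obsolete data and lose nothing on current data. The raw-signal
tier expresses drift as a signature-band swap only; drift experiments use
the feature tier.

What the generator does **not** emulate: real preictal heterogeneity
across seizures, artefacts (muscle, electrode pops), non-Gaussian feature
marginals, circadian structure, and long-range dependence. Passing tests
therefore demonstrate that the machinery is correct and that the adapters
recover planted drift — not that comparable performance would be reached
on clinical recordings.

## Known limitations

* The one-sample t-test treats the achieved sensitivity as a fixed
  constant. With few tested seizures (sensitivity restricted to coarse
  fractions) and an uninformative classifier whose output rate hovers near
  the Firing Power threshold, the validation scheme becomes
  anticonservative — false "above chance" verdicts well above the nominal
  level. With chance-level predictors operating at the preictal base rate
  it is well calibrated; the type-I check in the test suite uses that
  regime and three tested seizures per patient.
* The xi-alpha estimate is an estimate, not a guaranteed bound (see above).
* The BLW early stop can miss a better window beyond the patience horizon;
  this is inherent to the search design.
* The CNN-based artefact removal used by the original recordings' curators
  is replaced here by configurable band-pass/notch filtering; no ICA or
  artefact-subspace methods are included.
* Multi-file recordings with gaps are handled by the `valid_mask`
  convention but the loaders read single continuous files.

## Problem sizes used in the shipped checks

Unit and acceptance tests run on compressed synthetic patients (one
channel, 2–3 h gaps, 4–5 seizures; feature-tier streams of roughly
4,000–7,000 epochs), 10–20 seeds per property, and 100 patients for the
surrogate-calibration rates. The acceptance script runs a six-patient
cohort per approach with a reduced grid (one cost, one feature count,
three SOPs), ten SOP-recovery seeds and five drift seeds. These sizes were
chosen so the whole battery completes in minutes on a single core while
keeping every property statistically decidable.
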