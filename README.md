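# driftseize

Patient-specific EEG seizure prediction with explicit adaptation to
**concept drift** — the slow or abrupt change of brain-signal statistics
(medication tapering, vigilance, circadian state) that degrades any
classifier trained once and left alone.

## Who this is for

Researchers building or benchmarking seizure-prediction pipelines on
long-term annotated scalp EEG, and anyone studying drift-adaptive
retraining schemes for biosignal classifiers. The package provides the
complete chain — signal I/O, feature extraction, iterative retraining,
alarm generation, statistical validation — plus a synthetic generator of
drifting EEG so every component is testable without access-restricted
clinical data.

## The method

For each patient with at least four *lead* seizures (≥ 4.5 h apart), EEG is
filtered, cut into 5-s epochs, and described by 59 univariate linear
features per channel (relative band powers δ, θ, α, β, γ₁–γ₄ and their 28
pairwise ratios, spectral edge frequency/power, alpha peak, total power,
mean frequency, db4 wavelet energies D1–D5, the four statistical moments,
Hjörth activity/mobility/complexity, decorrelation time).

Epochs in `[onset − (SPH+SOP), onset − SPH)` are labelled preictal, with the
seizure occurrence period SOP ∈ {10, …, 50} min searched per patient and a
fixed 10-min prediction horizon SPH. Models are linear SVMs retrained after
every seizure on the three most recent seizures (**Add-One-Forget-One**),
with hyperparameters (cost C, number of ANOVA-F–selected features, SOP)
chosen by leave-one-seizure-out grid search maximising √(S_ss · S_sp).
On top of the retraining, three drift-adaptation strategies are compared
with a non-adaptive control:

* **Backwards-Landmark Window (BLW)** — grows candidate training windows
  backwards in 1-h steps and keeps the window minimising a leave-one-out
  (ξα) error estimate, `|{i : αᵢR² + ξᵢ ≥ 1}| / n`;
* **Seizure-batch Regression (SbR)** — selects the combination of past
  seizure batches whose ridge-logistic weight vector has the smallest angle
  θ(w₁, w₂) = cos⁻¹(w₁·w₂ / ‖w₁‖‖w₂‖) to one fitted on the most recent
  seizure alone;
* **Dynamic Weighted Ensemble (DWE)** — one SVM per 1-h period, weighted by
  accuracy over the last two hours before the most recent seizure, combined
  by weighted voting.

Test-epoch outputs are smoothed by the **Firing Power** (moving average over
one SOP of epochs); an upward crossing of 0.5 raises an alarm followed by an
SOP-long refractory period. Performance is reported as seizure sensitivity
SS and FPR/h (refractory time excluded), and validated against **surrogate
time series**: onsets are redrawn 30 times uniformly within their interictal
intervals and a one-sample t-test (α = 0.05) asks whether the achieved
sensitivity beats the surrogate distribution.

## Worked example

A synthetic patient with five seizures two hours apart and a genuine 20-min
preictal signature, run through the BLW pipeline:

```r
library(driftseize)

spec <- synthetic_spec(n_channels = 1, n_seizures = 5, gap_hours = 2,
                       true_sop = 20, effect_size = 2, seed = 42)
fs <- generate_feature_stream(spec)
fs$features
#> <feature_matrix> 7500 epochs x 59 features (1 channels), 7500 valid

fs$annotations[, c("onset", "offset", "lead")]
#>   onset offset lead
#> 1  7200   7380 TRUE
#> 2 14580  14760 TRUE
#> 3 21960  22140 TRUE
#> 4 29340  29520 TRUE
#> 5 36720  36900 TRUE

cfg <- run_config("blw",
                  grid = hyper_grid(cost_grid = 2^-2, n_features_grid = 10,
                                    sop_grid = c(15, 20, 25)),
                  seed = 1)
report <- run_patient(fs$features, fs$annotations, cfg)
report
#> <performance_report> blw: SS 1.00, FPR/h 0.00, surrogate 0.00, validated
```

Five seizures give exactly two Add-One-Forget-One iterations (seizure 4
tested against 1–3, seizure 5 against 2–4). In both, the grid search
recovers the planted 20-min SOP, each test seizure is predicted by a single
alarm and no false alarms are raised; the surrogate mean sensitivity is 0,
so the patient is statistically validated (p < 0.05). `report$iterations`
holds the per-iteration selections (here SOP 20, C = 0.25, k = 10) for
hyperparameter-frequency reports via
`report_hyperparameter_frequencies()`.

Raw-signal work uses the same API: `generate_recording()` →
`basic_denoise()` → `segment_epochs()` → `extract_features()`, and
recordings round-trip through 16-bit EDF or CSV with a JSON annotation
sidecar (`read_recording()` / `write_recording()`). A thin command-line
front end lives in `inst/cli/driftseize.R`
(`simulate` / `run` / `report`).

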