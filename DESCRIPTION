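Package: driftseize
Title: Concept-Drift-Adaptive EEG Seizure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific EEG seizure prediction with explicit adaptation
    to concept drift. Implements the full pipeline: EDF/CSV ingestion of
    multichannel scalp EEG with seizure annotations, zero-phase filtering,
    5-second epoch segmentation, a 59-feature univariate battery (relative
    band powers, band ratios, spectral edge, wavelet energies, statistical
    moments, Hjorth parameters, decorrelation time), SVM classification with
    Add-One-Forget-One retraining and leave-one-seizure-out hyperparameter
    search, three drift-adaptation strategies (Backwards-Landmark Window,
    Seizure-batch Regression, Dynamic Weighted Ensemble) plus a control
    pipeline, Firing Power alarm regularisation with refractory bookkeeping,
    and surrogate time-series statistical validation. A synthetic generator
    produces drifting multichannel EEG recordings and feature streams for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
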