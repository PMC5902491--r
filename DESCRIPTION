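Package: boldhurst
Title: Hurst-Exponent Features of Resting-State BOLD Signals for MCI
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise Hurst-exponent estimation of resting-state BOLD
    time series by rescaled-range (R/S) analysis, with atlas-based ROI
    feature extraction and nested leave-one-out support-vector-machine
    classification of mild cognitive impairment versus healthy controls.
    Includes an exact fractional Gaussian noise simulator (circulant
    embedding with a Durbin-Levinson fallback) for building synthetic
    cohorts with known ground-truth Hurst structure, temporal cleaning
    (detrending, nuisance regression, band-pass filtering), two-sample
    t-test plus Fisher-score feature selection restricted to training
    folds, and RBF-kernel SVM grid search with retention-stability and
    ROC reporting.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
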