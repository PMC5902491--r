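# boldhurst

Hurst-exponent features of resting-state BOLD signals for classifying mild
cognitive impairment (MCI) against healthy controls (HC).

Resting-state fMRI voxel series show long-range temporal dependence that a
fractional-Gaussian-noise model summarises with the Hurst exponent
H ∈ (0, 1) (H = 0.5: uncorrelated noise; H > 0.5: persistent dynamics;
spectral exponent β = 2H − 1). This package implements, as tested library
code plus a small scripted analysis, the full pipeline that turns 4D BOLD
volumes into an MCI/HC classifier:

1. **Temporal cleaning** — linear detrend, nuisance regression (motion,
   white-matter, ventricle signals), zero-phase 0.01–0.10 Hz band-pass.
2. **Voxelwise H estimation** by rescaled-range (R/S) analysis: mean R/S
   over non-overlapping segments at ~10 log-spaced window lengths; H is
   the log–log slope, optionally Anis–Lloyd bias-corrected.
3. **Atlas features** — per-ROI mean H over an integer-labelled parcellation
   (e.g. the 246-parcel brainnetome scheme), stacked into a
   subjects × ROIs matrix.
4. **Nested classification** — per-training-fold feature selection
   (two-sample pooled t-test p < 0.05 uncorrected, Fisher-score
   FS = [n₁(m₁−m)² + n₂(m₂−m)²] / [n₁σ₁² + n₂σ₂²] ranking), RBF-SVM over
   the 33 × 33 grid γ, C ∈ {2⁻⁸, 2⁻⁷·⁵, …, 2⁸} under leave-one-out CV,
   with confusion metrics, Mann–Whitney AUC, retention-stability reporting
   (stable = retained in ≥ 95% of folds) and a seeded holdout variant.

An exact fractional-Gaussian-noise simulator (circulant embedding, with a
Durbin–Levinson fallback) generates synthetic cohorts with known
ground-truth Hurst structure, so every stage is testable against a known
answer. See `vignettes/methods.Rmd` for the model, parameter choices,
estimator calibration and the known biases of the grid-search protocol.

## Worked example

```r
library(boldhurst)

spec <- cohort_spec(n_mci = 30, n_hc = 30, n_rois = 60, voxels_per_roi = 27,
                    n_timepoints = 229, baseline_H = 0.7, delta_H = -0.15,
                    affected_rois = 1:15, noise_sd = 0.1, seed = 501)
co   <- simulate_cohort(spec)
mask <- co$atlas > 0
maps <- lapply(co$bold, function(b)
  hurst_map(clean_volume(b, mask, tr = 2, band = c(0.01, 0.10)), mask))
fm   <- build_feature_matrix(maps, co$atlas, co$participants)
cv   <- grid_search(fm)   # 33 x 33 grid, LOOCV, per-fold selection
print(cv)
#> Nested LOOCV (radial kernel): accuracy 100.0%, sensitivity 100.0%,
#> specificity 100.0%, AUC 1.000
#>   best point gamma = 0.015625, C = 0.0441942; 17 stable feature(s) at
#>   threshold 57/60 folds
```

The grid-maximum accuracy is 100% because the injected effect (ΔH = −0.15
in ROIs 1–15) survives cleaning as a ≈ −0.04 shift in estimated ROI-mean
H, many standard errors wide once 27 voxels are averaged. The stable
feature set (retained in ≥ 57 of 60 folds) recovers all 15 affected ROIs
plus 2 false positives. On the matching null cohort (`delta_H = 0`) the
same protocol returns a grid-maximum accuracy of 58.3% — the optimism of
reporting a maximum over 1089 grid points — while the per-point median,
also returned in `cv$per_point_accuracy`, is 0.33.

The same workflow, script by script (cohort → features → classification →
estimator calibration), is under `analysis/01...04_*.R`; each writes its
tables to `results/`.

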