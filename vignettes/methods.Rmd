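---
title: "Hurst-exponent BOLD features and nested SVM classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurst-exponent BOLD features and nested SVM classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldhurst)
```

## The model

Resting-state BOLD signals show long-range temporal dependence that is well
summarised by the Hurst exponent $H \in (0,1)$ of a fractional-Gaussian-noise
(fGn) model: $H = 0.5$ is uncorrelated noise, $H > 0.5$ persistent
("fractal", slowly wandering) dynamics, $H < 0.5$ anti-persistence. $H$ maps
onto the spectral power-law exponent through $\beta = 2H - 1$. The working
hypothesis behind this package is that mild cognitive impairment (MCI)
alters the temporal complexity of regional BOLD signals, so per-region $H$
can serve as a discriminative feature for classifying MCI patients against
healthy controls (HC).

The pipeline is: temporal cleaning of each voxel series, voxelwise $H$
estimation by rescaled-range (R/S) analysis, atlas-parcel averaging into a
subjects $\times$ ROIs feature matrix, then a soft-margin SVM with
per-training-fold univariate feature selection, evaluated by leave-one-out
cross-validation (LOOCV) over a $33 \times 33$ hyperparameter grid.

## Rescaled-range estimation

For a window length $n$ the series is cut into $\lfloor N/n \rfloor$
non-overlapping segments (the remainder is discarded). In each segment the
cumulative deviations from the segment mean give a range
$R = \max Z - \min Z$, and $S$ is the segment standard deviation in the
population convention (divide by $n$; fixed so results are bit-stable).
Segments with $S = 0$ are skipped; a scale with no valid segment is
dropped, and a voxel left with fewer than three scales is flagged
undefined rather than zeroed. The slope of $\log_2 \overline{R/S}$ against
$\log_2 n$ over roughly ten log-spaced windows from 10 to
$\lfloor N/2 \rfloor$ is $\hat H$. With 229 volumes this grid
(10, 13, 17, 22, 29, 38, 50, 66, 87, 114) keeps at least two segments at
every scale. Base-2 logarithms fix the reported intercept; the slope is
base-invariant.

R/S is upward-biased in finite samples because the expected rescaled range
of white noise is not yet on its asymptotic $\sqrt{n \pi / 2}$ power law at
small $n$. The optional Anis–Lloyd correction subtracts the closed-form
white-noise expectation (with the $(n - \tfrac12)/n$ small-sample factor)
in the log domain and re-centres the fit at $0.5$. It is **off by
default** — the headline protocol does not use it — and switched on where an
unbiased white-noise anchor matters.

Calibration against the exact fGn sampler (50 series per $H$, $N = 1024$;
`analysis/04_estimator_calibration.R` reproduces the table) shows the
trade-off: raw estimates run $+0.10$ high at $H = 0.3$ and $-0.07$ low at
$H = 0.9$; the correction centres white noise at $0.48$–$0.49$ and removes
most of the low-$H$ bias, but *amplifies* the high-$H$ attenuation to about
$-0.13$ at $H = 0.9$, because the subtracted expectation is the white-noise
one, not the (H-dependent) fGn one. Both variants are strictly monotone in
the true $H$. Users comparing groups should rely on the contrast, which is
insensitive to the shared bias, rather than on absolute $H$ values.

## The fGn generator as ground truth

`simulate_fgn()` draws exact fGn via circulant embedding of the
autocovariance $\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$;
eigenvalues are obtained by FFT, so draws are $O(n \log n)$ and follow the
target law exactly — important because the estimator's bias is itself under
test. If the embedding ever produced negative eigenvalues the sampler
would fall back to the exact sequential Durbin–Levinson recursion (for the
fGn autocovariance this is a theoretical safeguard; the tests exercise the
fallback sampler directly and check both against the closed-form
autocovariance using uncentred sample moments, which avoid the substantial
mean-estimation bias of long-memory series).

`simulate_cohort()` builds the study conditions: each subject is a 4D
volume on a block atlas in which every in-atlas voxel carries an
independent fGn series plus white measurement noise
(`noise_sd = 0.1` against unit fGn variance, i.e. 1% noise power — "low"
scanner noise after spatial preprocessing). Defaults encode a typical
acquisition: 229 volumes at TR = 2 s, 246 parcels, baseline $H = 0.7$
(persistent BOLD dynamics), and a $-0.15$ reduction of $H$ in affected
ROIs of MCI subjects. The direction of the shift is a free choice — the
pipeline must detect either sign — and its magnitude cannot be calibrated
to any reported effect size, so $0.15$ was fixed once as a moderate,
realistic regional effect. What the generator deliberately omits:
hemodynamic response shape, spatial autocorrelation, motion and scanner
artifacts, between-subject variance in baseline $H$. Passing tests
therefore demonstrate the *procedure* (estimation, selection, leakage-free
CV), not performance on real data.

## Temporal cleaning

Cleaning follows the standard resting-state order — linear detrend,
nuisance regression (with an intercept, so residuals are centred), then a
0.01–0.10 Hz band-pass — each applied independently per masked voxel. The
filter is an ideal frequency-domain boxcar with inclusive band edges: no
filter family is canonical here, the ideal filter is common in rs-fMRI
toolchains, and its unit-gain passband is directly testable. All three
steps are linear operators, which the tests assert. Global-signal
regression is not performed. One consequence worth knowing: band-limiting
an fGn series compresses its R/S slope toward 0.5, so the group contrast
recovered downstream is attenuated relative to the injected $\Delta H$
(about $-0.04$ recovered from $-0.15$ injected under the default
conditions) — still many standard errors wide after averaging 27 voxels
per parcel.

## Feature selection and the Fisher score

Within each training fold every ROI feature is tested with a two-sample
pooled-variance t-test (two-tailed, $p < 0.05$, uncorrected — deliberately
no multiplicity correction, matching mass-univariate practice for feature
screening); features passing the filter are ordered by descending Fisher
score
$$FS = \frac{n_1 (m_1 - m)^2 + n_2 (m_2 - m)^2}{n_1 \sigma_1^2 + n_2 \sigma_2^2},$$
with population group variances. The t-test is the retention rule and the
Fisher score the ranking/reporting statistic; a Fisher cutoff on top of
the t-filter is not applied, a reading that reproduces per-fold retention
counts of the observed order (about 14–17 of 246) under moderate effects.
If nothing passes, the fold falls back to the single best-Fisher feature
(a fold must emit a prediction) and warns. Selection sees only the
training view; the leakage tests poison held-out rows with sentinels and
require bit-identical fold internals.

## SVM grid search and its biases

The classifier is a soft-margin SVM (libsvm via e1071) with RBF kernel
$K(x, x') = e^{-\gamma \|x - x'\|^2}$ (the decaying form; a growing
exponential is not a valid kernel). Retained features are z-scored with
training-fold means/SDs — RBF kernels on raw scales make the fixed
$2^{-8}..2^8$ grid meaningless. Both $\gamma$ and $C$ range over powers of
two from $2^{-8}$ to $2^8$ in half-exponent steps (33 values each); the
reported headline is the grid-maximum LOOCV accuracy, with deterministic
tie-breaking toward the smallest $C$ then smallest $\gamma$ (least complex
model). MCI is the positive class; the ROC pools the per-fold decision
values at the best point and the AUC is the tie-aware Mann–Whitney
concordance probability. Features retained in at least
$\lceil 0.95 \times \text{folds} \rceil$ folds (118 of 124) form the
stable set, reported with mean Fisher scores.

Two biases of this protocol are surfaced rather than hidden, and the full
per-point accuracy table is always returned so users can report unbiased
summaries:

* **Optimism of the grid maximum.** Selecting $(\gamma, C)$ by maximal
  LOOCV accuracy over 1089 points overfits the folds; under a null cohort
  the best point sits above chance even though no signal exists.
* **Pessimism of balanced LOOCV.** With equal groups, each fold's training
  set under-represents the held-out class by one subject; at degenerate
  grid points (very small $C$, extreme $\gamma$) the SVM predicts the
  training majority, i.e. systematically the *wrong* class, driving
  per-point accuracy toward zero there. The median over the whole grid
  under a null cohort therefore falls *below* the naive binomial chance
  band — a property of the protocol, not an implementation artifact.

The holdout variant splits the cohort once (stratified, seeded), picks
$(\gamma, C)$ by an internal two-fold cross-prediction inside the training
subset (each half selects its own features and predicts the other), then
scores a final model, with selection re-fit on the full training subset,
once on the untouched test subset.

## Problem sizes and numerical choices

The shipped analyses and tests run at sizes chosen to exercise every code
path at desk scale: estimator calibration at $N = 1024$ with 50–100
series, and end-to-end cohorts of 30 + 30 subjects on 60 parcels of 27
voxels (97,200 voxel series of length 229 per cohort). Cohorts, folds and
grids are bit-reproducible from a single master seed (per-subject
sub-seeds are derived from it; the caller's RNG stream is never
disturbed). Degenerate inputs fail loudly with typed conditions: constant
series, empty masks, rank-deficient confound designs (naming the collinear
columns), ROIs with no defined voxels, single-class training sets.

## Known limitations

Absolute $\hat H$ values inherit estimator bias (above) and the band-pass
attenuation; group contrasts are the reliable quantity. The generator's
independence assumptions (no spatial correlation, no subject-level $H$
variability) make classification easier than on real data, so accuracy on
synthetic cohorts is an upper bound on realism. The headline grid-maximum
accuracy is optimistic by construction; nested selection of $(\gamma, C)$
would remove it at ~33$\times$ the cost. The 246-parcel brainnetome atlas
itself is a user-supplied input; the block atlas only mimics its label
structure.
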