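---
title: "Methods: multimodal static and dynamic FNC classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal static and dynamic FNC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures
it implements, the assumptions they rest on, the tunable parameters and
their defaults, and the design choices made where the methodology was
genuinely open.

## The problem

Resting-state recordings from two subject groups (labelled HC and SZ
throughout) are summarized, per subject and per data source, as a
T × C matrix of component timecourses: C spatial brain-network
components (typically derived by group spatial ICA), each with T
samples. The fMRI source has T = 149 samples at 0.5 Hz (TR = 2 s) and
C = 38 retained components by default; each MEG band-limited envelope
source (delta, theta, alpha, beta, gamma) has T = 300 samples at an
effective 1 Hz and C = 32. Functional network connectivity (FNC) is the
pairwise correlation structure among these timecourses; the question is
whether per-subject FNC features support single-subject group
classification, and whether combining fMRI with MEG improves it.

All connectivity features live in the *pair space* of the upper
triangle: pairs (i, j), i < j, in row-major order. This single
convention is enforced by `pair_index()` / `vectorize_upper()` across
static and dynamic pipelines, so features from different stages can
never be silently misaligned. C = 38 gives 703 pairs, C = 32 gives 496.

## Static FNC

Timecourses are despiked (samples deviating from a running median of
window 5 by more than 4 MADs are replaced by that median — the window
and multiplier are package choices, documented because the upstream
convention they emulate is not published in detail), then correlated
pairwise over their full length and Fisher-transformed,
z = arctanh(r), with |r| clipped at 1 − 1e−7 so degenerate synthetic
inputs cannot produce infinities. Zero-lag correlation is the default;
an optional max-lag mode (the signed correlation of maximal magnitude
over lags −L..L, default L = 3 when enabled) exists because lagged
coupling is sometimes of interest, but L = 0 is the default since the
two conventions disagree only when couplings are delayed.

Feature selection, run inside each cross-validation fold on training
subjects only, is a Welch two-sample t-test per pair followed by
Benjamini–Hochberg FDR control at q = 0.05. Welch (unequal variance)
was chosen because the groups are independent samples of nearly equal
size; the variance-pooled test is a special case and agrees when
variances match. If no pair survives FDR the selector falls back to the
single best pair by p-value (with a warning) so downstream classifiers
always receive input; the fallback is rare outside null data.

## Dynamic FNC

A tapered window of width w = 31 samples (step 1) slides along the
despiked timecourses: a rectangle convolved with a unit-sum Gaussian of
σ = 3 samples, center-cropped to w and renormalized to sum w. With
T = 149 this yields 119 windows; with T = 300, 270 windows. The same
window length is used for fMRI and MEG by default (both are configurable
per modality); using one length across modalities is a simplification
with known cost to MEG dynamics.

Within each window a weighted covariance (weights = taper, weight-sum
normalization) is regularized through the graphical LASSO: maximize
log det Θ − tr(SΘ) − λ‖Θ‖₁ over the off-diagonal entries of the
precision Θ, solved by block coordinate descent (tolerance 1e−6 on the
parameter change). The regularized covariance Θ⁻¹ is converted to a
correlation matrix and Fisher-transformed; those pair vectors are the
windowed FNC. Composing "windowed correlation" with "covariance
estimated from the regularized inverse covariance" honors both ways the
procedure is usually described. The penalty λ is selected per subject:
windows are split into 3 contiguous blocks (contiguity limits temporal
leakage between folds), the model is fit on the pooled training-fold
covariance, and the held-out Gaussian log-likelihood
log det Θ − tr(S_test Θ) is averaged; the λ maximizing it wins, ties
going to the larger (sparser) value. The default grid is 10 points
log-spaced on [0.01, 1]. None of grid, fold count, or tie rule is fixed
by convention elsewhere; these are package defaults chosen to be
deterministic and cheap.

Connectivity *states* are k-means centroids (Euclidean distance in
Fisher-z pair space; correlation and cosine metrics are options, since
the metric choice has repeatedly been found not to matter) fit per
group on all training-subject windows, with seeded k-means++
initialization and 10 restarts, keeping the lowest-inertia solution.
Empty clusters are re-seeded at a random window and logged. The state
count defaults to k = 5 per group; alternatively `validity_elbow()`
scans a k range and picks the elbow of the validity index (mean
within-cluster distance / mean between-centroid distance),
operationalized as the largest discrete second difference of the index
curve — "elbow" itself names only a shape, so the package commits to
this concrete rule. On curves with no positive curvature it returns the
smallest k with a warning.

Each subject's feature vector is the mean over windows of the OLS
coefficients of the window's pair vector regressed on the 2k group
centroids (HC states first, then SZ). Window and centroid vectors are
mean-centered in pair space and no intercept is fit — with 2k
correlated, non-orthogonal regressors an intercept would absorb the
overall connectivity level that the centering already removes. A
rank-deficient centroid design (possible when two states collapse)
falls back to a 1e−6 ridge with a warning.

## Classification and ensembling

Leave-one-out cross-validation: each subject in turn is held out, all
feature selection and state fitting happens on the remaining subjects,
and the held-out subject is projected onto the selected pairs or fitted
centroids. Three classifiers are run on features standardized by
training-fold statistics: a linear discriminant (pooled covariance with
Ledoit–Wolf shrinkage toward a scaled identity whenever features
outnumber the smaller class or the covariance is ill-conditioned),
Gaussian naive Bayes (per-class diagonal Gaussians with a variance
floor of 1e−3 of the mean feature variance, preventing degenerate
likelihoods on constant features), and a soft-margin SVM with Gaussian
RBF kernel (cost 1, kernel width 1/d on standardized features) via
**e1071**. Decision values are signed toward SZ; an exactly zero value
resolves to HC, the first class in the fixed order.

Multimodal combination happens two ways: *feature concatenation*
(selection per source, then column-wise fusion, e.g. fMRI+delta) and
*majority voting* across per-source predictions with equal weights.
Vote ties are broken by the larger mean member confidence, then by
fixed class order (HC), and flagged; the canonical panels are odd-sized
so ties arise only in custom configurations. Voting is ensembled
within one classifier across sources (per-classifier panels), matching
how the accuracies are tabulated; cross-classifier ensembling is
possible but off by default.

## Group spatial ICA stage

The decomposition stage is optional — the FNC pipelines accept
component timecourses from any source. When used: per-subject PCA
(economy-size SVD, 100 components by default at full scale), group
reduction by EM-PCA (iterative low-rank estimation whose converged
subspace provably matches direct PCA on small instances — the package
tests this — while avoiding a dense decomposition of the stacked data),
then infomax ICA with the logistic nonlinearity and natural gradient
(initial learning rate 0.01, annealing ×0.9 on weight blow-up,
stopping tolerance 1e−7, 512 passes max). Stability selection follows
the ICASSO recipe: 20 runs from random starts, components pooled and
clustered by absolute Pearson correlation with average-linkage
agglomerative clustering cut at C_ic clusters, cluster quality = mean
intra-cluster minus mean extra-cluster similarity, and the run best
matching the cluster centrotypes is returned. Back-reconstruction of
subject timecourses uses dual (spatial-temporal) regression — a
least-squares projection of subject data onto group maps — chosen over
the GICA3 alternative because it has an exact forward-model oracle and
an identical interface. Component screening replaces expert visual
review with two deterministic spectral rules on a Welch spectrum: the
low/high-frequency power ratio (power below 0.10 Hz over power in
0.15–0.25 Hz, threshold 2) and the dynamic range (peak minus
post-peak minimum on a unit-power scale, threshold 0.01).

## The synthetic cohort generator

The generator exists so that every downstream stage is testable with
known ground truth; its defaults are the study conditions. A cohort has
46 SZ and 45 HC subjects; each subject has one fMRI source (149 × 38)
and five MEG band sources (300 × 32). Per source, a baseline
correlation matrix is drawn (low-rank factor structure, typical
off-diagonal magnitude ≈ 0.25); the SZ group differs from HC only at
planted effect pairs, perturbed by a signed Δr and repaired to the
nearest SPD correlation matrix by eigenvalue clipping at 1e−6 and
re-normalization to unit diagonal. The default effect layout plants
|Δr| = 0.3 in block patterns: 12 pairs in fMRI, 9 in delta, 4 in
alpha, 22 in beta and none in theta or gamma — emulating the
qualitative picture of band-specific frontal/default-mode
hyper- and hypo-connectivity blocks without any anatomical claim
(pair indices are arbitrary).

Dynamics are Markov-switching Gaussian covariance regimes: a
first-order chain over 5 states per group (stay probability 0.9),
each state a shared random perturbation of the baseline (state
perturbations avoid the planted pairs) with the group's planted
differences re-applied, so the dFNC pipeline's own assumption —
distinct recurring windowed-covariance states — is literally true and
parameter recovery is a meaningful test. Each sample mixes the active
state's draw with an i.i.d. stationary component carrying the static
structure (weight 0.5), and an exponential low-pass filter is applied
per modality (coefficient 0.6 for fMRI, mimicking hemodynamic
sluggishness; 0.3 for MEG envelopes). Because the same filter acts on
every component, zero-lag correlations are unaffected, which the test
suite asserts.

What the generator does *not* emulate: biophysical BOLD or neural-mass
dynamics, spatial (voxel-level) structure, physiological noise,
motion, or scanner artifacts. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its own model class — planted
effects are recovered, selection is FDR-calibrated, classification is
unbiased under the null — not performance on real recordings, whose
headline accuracies cannot be reproduced without the original subject
data.

## Numerical choices and degenerate inputs

- SPD repair = eigenvalue clipping at 1e−6 + unit-diagonal
  renormalization; planting that moves a repaired value more than 0.1
  from its target is an error advising a smaller Δr (state matrices
  use a softer clip-and-tolerance since they are auxiliary).
- Graphical lasso adds a 1e−8 ridge to a non-PSD input, solves λ = 0 by
  direct inversion, and errors (rather than returning junk) on
  non-convergence.
- Weighted covariance with a single effective sample returns the zero
  matrix; a zero-variance column otherwise is an error naming the
  column.
- Fisher z clips |r| at 1 − 1e−7; despiking a constant series is a
  no-op; k-means empty clusters are re-seeded and logged.
- Every stochastic operation takes an explicit seed; the pipeline
  derives per-stage and per-fold seeds from the master seed by fixed
  integer offsets, so end-to-end runs are bit-reproducible.

## Problem sizes used in validation

The validation suites run at reduced scale so that the full suite
completes in minutes: oracle-equivalence checks use 5–6-dimensional
instances (graphical lasso vs an independent ADMM solver, BH-FDR vs
brute-force step-up, centroid regression vs normal equations, PCA and
EM-PCA vs a dense eigensolver); state and state-count recovery use
orthogonal equal-norm planted centroids at ≥ 5× separation over 10
seeds; calibration uses 200 pure-null cohorts (false-discovery
proportion) and 20 label-permuted cohorts (LOOCV chance band); the
end-to-end classification checks use a Δr = 0.8, 20-per-group cohort
with 8 components in static and dynamic mode, and a
three-source complementary-signal cohort for the ensemble property.
ICA recovery is scored by the Amari index on seeded five-source
Laplace mixtures. Full-scale (91 × 38/32-component) cohorts are
exercised for the dimensionality and feature-selection counts in
`scripts/acceptance.R`.

## Known limitations

- The graphical lasso and infomax are plain-R implementations tuned for
  the moderate dimensions of this problem (C ≤ ~40); very high model
  orders would want a compiled solver.
- The elbow rule (max second difference) assumes the validity index
  flattens after the true k; on smoothly decaying curves it returns
  the smallest candidate with a warning.
- LOOCV with per-fold selection is honest but high-variance; no nested
  hyperparameter search is performed (classifier defaults are fixed).
- The generator's group difference is a mean shift in correlation;
  group differences in variance, spectra or state dwell times are not
  planted and hence not tested.
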