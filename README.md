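# mmfnc — multimodal static and dynamic FNC classification

`mmfnc` implements a complete framework for two-group classification of
subjects from multimodal resting-state brain network timecourses —
fMRI component timecourses plus band-limited MEG envelope timecourses
(delta, theta, alpha, beta, gamma) — using **functional network
connectivity (FNC)**: the pairwise correlation structure among
ICA-derived brain network components. It is aimed at researchers in
functional connectomics who want a tested, scriptable re-implementation
of the static/dynamic FNC classification methodology, exercised
end-to-end on synthetic cohorts with known ground truth.

## What it computes

For each subject and data source the package derives connectivity
features in the upper-triangle *pair space* of C components
(C(C−1)/2 pairs; 703 for C = 38, 496 for C = 32):

- **Static FNC** — Pearson correlation r_ij over the full (despiked)
  timecourses, Fisher-transformed (z = arctanh r). Feature selection per
  cross-validation fold: Welch two-sample t-tests per pair between
  groups, Benjamini–Hochberg FDR at q = 0.05.
- **Dynamic FNC** — a tapered sliding window (width w = 31 samples,
  step 1, rectangle convolved with a Gaussian of σ = 3) slides over the
  timecourses; each windowed covariance is regularized through the
  graphical LASSO (L1 penalty λ on the off-diagonal precision, chosen
  per subject by cross-validated held-out Gaussian log-likelihood), and
  the regularized covariance is converted to Fisher-z correlations.
  T = 149 fMRI samples give 119 windows; T = 300 MEG samples give 270.
  Per fold, k-means (k-means++ seeding, 10 restarts) fits k = 5
  connectivity states per group; each subject's windows are regressed on
  the 2k group centroids and the mean betas form a 2k = 10-dimensional
  feature vector. The state count can be chosen by the elbow of the
  within/between cluster validity index.
- **Classification** — leave-one-out cross-validation with strict fold
  hygiene (selection and centroids fit on training subjects only) using
  a linear discriminant (Ledoit–Wolf shrinkage when features outnumber
  subjects), Gaussian naive Bayes, and an RBF-kernel SVM.
- **Ensembling** — feature concatenation across sources (e.g.
  fMRI+delta) and equal-weight majority voting across per-source
  predictions.
- **Group spatial ICA** (optional stage) — subject PCA, group EM-PCA,
  repeated infomax ICA with ICASSO-style stability clustering,
  dual-regression back-reconstruction, and spectral screening of
  artifactual components (low/high-frequency power ratio and dynamic
  range). The FNC stages accept externally derived component
  timecourses directly, so this stage can be bypassed.
- **Synthetic cohorts** — a generator plants signed group differences
  Δr in chosen connectivity pairs and Markov-switching state
  covariances, yielding 91-subject (46 SZ / 45 HC by default) cohorts
  with exportable ground truth for power, calibration and recovery
  studies.

## Worked example

```r
library(mmfnc)
ep <- data.frame(source = c("fmri", "fmri", "delta"),
                 i = c(1, 1, 2), j = c(2, 3, 4), dr = 0.4)
cfg <- simulation_config(n_sz = 12, n_hc = 12, C_fmri = 10, C_meg = 8,
                         T_fmri = 149, T_meg = 150, bands = "delta",
                         effect_pairs = ep, n_states = 3, seed = 42)
sim <- simulate_study(cfg)
res <- run_pipeline_loocv(sim$dataset, mode = "static",
                          sources = list("fmri", "delta", c("fmri", "delta")),
                          seed = 1)
print(res)
#> LOOCV static-FNC classification: 24 subjects, sources: fmri, delta, fmri+delta
#>   classifier delta  fmri fmri+delta
#> 1        ldc 91.67 91.67      95.83
#> 2        nbc 91.67 91.67      95.83
#> 3       nsvm 91.67 91.67     100.00
#> 4    average 91.67 91.67      97.22
```

The table reports LOOCV accuracy (%) per classifier and source; here
two weak planted effects (Δr = 0.4) in fMRI and one in the MEG delta
band give ~92% per-modality accuracy, and concatenating the selected
fMRI and delta features raises it to ~97% — the multimodal gain the
framework is designed to measure. `run_all()` executes the whole
layout (simulate → static and dynamic FNC → per-source and fused
LOOCV → ensembles) from a single, YAML-configurable entry point, and
`inst/cli/mmfnc.R` exposes `simulate` and `run-all` from the shell.

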