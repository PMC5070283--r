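Package: mmfnc
Title: Static and Dynamic Functional Network Connectivity Classification
    for Multimodal Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for two-group classification from multimodal
    (fMRI and MEG band-limited envelope) resting-state component
    timecourses using functional network connectivity (FNC). Implements
    group spatial ICA (two-stage PCA with EM-PCA, repeated infomax with
    ICASSO-style stability selection, dual-regression back-reconstruction,
    spectral component screening), static FNC with Fisher-z transformation
    and FDR-controlled feature selection, dynamic FNC from tapered sliding
    windows with graphical-LASSO regularized precision estimation and
    per-subject penalty cross-validation, k-means connectivity-state
    clustering with centroid-regression features, leave-one-out
    cross-validated classification (linear discriminant, naive Bayes,
    RBF-kernel SVM), and majority-vote multimodal ensembling. Includes a
    synthetic cohort generator with planted static group differences and
    Markov-switching connectivity states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
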