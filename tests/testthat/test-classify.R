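test_that("LOOCV folds partition the cohort with every subject tested once", {
  ids <- sprintf("s%02d", 1:91)
  labels <- rep(c("HC", "SZ"), length.out = 91)
  folds <- loocv_folds(ids, labels)
  expect_length(folds, 91)
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 90))
  expect_setequal(vapply(folds, function(f) f$test, ""), ids)
  for (f in folds[c(1, 45, 91)]) {
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(loocv_folds(ids[1:2], labels[1:2]), "3 subjects")
  expect_error(loocv_folds(ids[1:5], rep("HC", 5)), "single-class")
})

test_that("all three classifiers separate a 10-sigma toy problem", {
  set.seed(61)
  n <- 20
  Xtr <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = 10), n, 2))
  ytr <- rep(c("HC", "SZ"), each = n)
  Xte <- rbind(c(0, 0), c(10, 10), c(-1, 1), c(11, 9))
  want <- c("HC", "SZ", "HC", "SZ")
  for (kind in c("ldc", "nbc", "nsvm")) {
    pr <- fit_predict(classifier_spec(kind), Xtr, ytr, Xte)
    expect_equal(pr$label, want, info = kind)
  }
})

test_that("naive Bayes matches the closed-form Bayes rule on its own model", {
  set.seed(62)
  mu1 <- c(0, 0); mu2 <- c(1.5, -1)
  s1 <- c(1, 2); s2 <- c(0.5, 1)
  n <- 400
  Xtr <- rbind(sweep(matrix(rnorm(n * 2), n, 2), 2, s1, "*"),
               sweep(sweep(matrix(rnorm(n * 2), n, 2), 2, s2, "*"), 2, mu2, "+"))
  ytr <- rep(c("HC", "SZ"), each = n)
  Xte <- rbind(sweep(matrix(rnorm(250 * 2), 250, 2), 2, s1, "*"),
               sweep(sweep(matrix(rnorm(250 * 2), 250, 2), 2, s2, "*"), 2, mu2, "+"))
  pr <- fit_predict(classifier_spec("nbc"), Xtr, ytr, Xte)
  # oracle: exact posterior with the true class densities
  ll <- function(X, mu, s) {
    rowSums(sapply(1:2, function(j) dnorm(X[, j], mu[j], s[j], log = TRUE)))
  }
  bayes <- ifelse(ll(Xte, mu2, s2) > ll(Xte, mu1, s1), "SZ", "HC")
  expect_gt(mean(pr$label == bayes), 0.97)
})

test_that("unshrunk LDC agrees with MASS::lda on well-conditioned data", {
  set.seed(60)
  n <- 50
  Xtr <- rbind(matrix(rnorm(n * 3), n, 3),
               sweep(matrix(rnorm(n * 3), n, 3), 2, c(1.5, -1, 0.5), "+"))
  ytr <- rep(c("HC", "SZ"), each = n)
  Xte <- rbind(matrix(rnorm(40 * 3), 40, 3),
               sweep(matrix(rnorm(40 * 3), 40, 3), 2, c(1.5, -1, 0.5), "+"))
  pr <- fit_predict(classifier_spec("ldc", shrinkage = 0), Xtr, ytr, Xte)
  ref <- MASS::lda(Xtr, grouping = ytr)
  want <- as.character(predict(ref, Xte)$class)
  expect_equal(pr$label, want)
})

test_that("LDC falls back to shrinkage when features outnumber subjects", {
  set.seed(63)
  Xtr <- matrix(rnorm(10 * 30), 10, 30)
  Xtr[6:10, 1] <- Xtr[6:10, 1] + 5
  ytr <- rep(c("HC", "SZ"), each = 5)
  pr <- fit_predict(classifier_spec("ldc"), Xtr, ytr, Xtr)
  expect_gt(mean(pr$label == ytr), 0.9)
})

test_that("zero-variance features are dropped with a warning", {
  set.seed(64)
  Xtr <- cbind(rnorm(10), rep(3, 10))
  Xtr[6:10, 1] <- Xtr[6:10, 1] + 8
  ytr <- rep(c("HC", "SZ"), each = 5)
  expect_warning(pr <- fit_predict(classifier_spec("ldc"), Xtr, ytr, Xtr),
                 "zero-variance")
  expect_equal(pr$label, ytr)
})

test_that("strong planted signal yields high LOOCV accuracy in static mode", {
  sim <- tiny_cohort(n_per_group = 12, C = 6, T_n = 100, dr = 0.6,
                     pairs = data.frame(i = c(1, 1, 2), j = c(2, 3, 3)),
                     seed = 71, base_strength = 0.1)
  r <- run_pipeline_loocv(sim$dataset, mode = "static", sources = "fmri",
                          seed = 2)
  avg <- r$accuracy$accuracy[r$accuracy$classifier == "average"]
  expect_gt(avg, 0.85)
  # accuracy table covers classifiers x sources plus the average rows
  expect_equal(nrow(r$accuracy), 4)
})

test_that("fold hygiene: the held-out subject cannot influence its own fold", {
  sim <- tiny_cohort(n_per_group = 5, C = 5, T_n = 60, seed = 72)
  ds1 <- sim$dataset
  ds2 <- ds1
  # corrupt one subject's data; predictions for OTHER subjects use folds
  # that include the corrupted one, so compare only the corrupted fold's
  # selected features, which must come from the unchanged training set
  victim <- names(ds1$subjects)[3]
  ds2$subjects[[victim]]$tcs$fmri$data <-
    ds2$subjects[[victim]]$tcs$fmri$data * 5 + 7
  r1 <- suppressWarnings(run_pipeline_loocv(ds1, mode = "static",
                                            sources = "fmri", classifiers = "ldc",
                                            seed = 4))
  r2 <- suppressWarnings(run_pipeline_loocv(ds2, mode = "static",
                                            sources = "fmri", classifiers = "ldc",
                                            seed = 4))
  expect_identical(r1$selected_features$fmri[[victim]],
                   r2$selected_features$fmri[[victim]])
})

test_that("subject ordering does not change the accuracy", {
  sim <- tiny_cohort(n_per_group = 6, C = 5, T_n = 80, dr = 0.5,
                     pairs = data.frame(i = 1, j = 2), seed = 73)
  ds <- sim$dataset
  perm <- sample(seq_along(ds$subjects))
  ds2 <- study_dataset(unname(ds$subjects[perm]))
  r1 <- suppressWarnings(run_pipeline_loocv(ds, mode = "static",
                                            sources = "fmri", classifiers = "nbc",
                                            seed = 1))
  r2 <- suppressWarnings(run_pipeline_loocv(ds2, mode = "static",
                                            sources = "fmri", classifiers = "nbc",
                                            seed = 1))
  expect_equal(r1$accuracy$accuracy, r2$accuracy$accuracy)
})
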