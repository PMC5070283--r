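test_that("taper is symmetric, center-peaked, normalized, with flat limits", {
  spec <- make_taper(31, 3)
  w <- spec$weights
  expect_equal(w, rev(w))
  expect_equal(w[16], max(w))  # center is on the maximal plateau
  expect_equal(sum(w), 31)
  expect_lt(max(w), 31)  # actually tapered
  flat <- make_taper(11, 0)
  expect_equal(flat$weights, rep(1, 11))
  expect_warning(make_taper(7, 50), "near-flat")
  expect_error(make_taper(2, 3), ">= 3")
})

test_that("window counts follow floor((T-w)/step)+1 exactly", {
  spec <- make_taper(31, 3)
  expect_equal(nrow(sliding_windows(149, spec)), 119)
  expect_equal(nrow(sliding_windows(300, spec)), 270)
  expect_equal(nrow(sliding_windows(31, spec)), 1)
  expect_error(sliding_windows(30, spec), "shorter")
  # brute force over a grid of (T, w, step)
  for (T_n in c(31, 50, 64, 100, 149)) {
    for (w in c(5, 10, 31)) {
      for (s in c(1, 2, 5)) {
        spec2 <- make_taper(w, 1, step = s)
        brute <- length(seq(1, T_n - w + 1, by = s))
        expect_equal(nrow(sliding_windows(T_n, spec2)), brute)
      }
    }
  }
})

test_that("weighted covariance matches a brute-force double loop", {
  set.seed(41)
  X <- matrix(rnorm(20 * 4), 20, 4)
  wts <- runif(20)
  S <- weighted_covariance(X, wts)
  nw <- wts / sum(wts)
  mu <- colSums(X * nw)
  brute <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    brute[a, b] <- sum(nw * (X[, a] - mu[a]) * (X[, b] - mu[b]))
  }
  expect_equal(S, brute, tolerance = 1e-10)
  expect_equal(weighted_covariance(X, rep(1, 20)),
               cov(X) * (19 / 20), tolerance = 1e-10)
  onehot <- c(1, rep(0, 19))
  expect_equal(weighted_covariance(X, onehot), matrix(0, 4, 4))
  Xz <- X; Xz[, 2] <- 5
  expect_error(weighted_covariance(Xz, wts), "zero-variance")
})

test_that("graphical lasso matches an independent ADMM solver", {
  set.seed(42)
  for (r in 1:20) {
    S <- random_spd(5)
    g <- graphical_lasso(S, 0.1)
    expect_lt(max(abs(g$theta - admm_glasso(S, 0.1))), 1e-4)
  }
})

test_that("graphical lasso honors its analytic limits", {
  set.seed(43)
  S <- random_spd(5, ridge = 1)
  g0 <- graphical_lasso(S, 0)
  expect_lt(max(abs(g0$theta - solve(S))), 1e-4)
  lam <- max(abs(S - diag(diag(S)))) + 1e-9
  gT <- graphical_lasso(S, lam)
  off <- gT$theta; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  expect_equal(diag(gT$theta), 1 / diag(S), tolerance = 1e-10)
  expect_error(graphical_lasso(S, -1), "lambda")
})

test_that("glasso sparsity is non-increasing in lambda", {
  set.seed(44)
  for (r in 1:20) {
    S <- random_spd(6)
    nz <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 1),
                 function(l) sum(abs(graphical_lasso(S, l)$theta[upper.tri(S)]) > 1e-8),
                 0)
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("penalty cross-validation prefers interior lambda on sparse models", {
  set.seed(45)
  Theta <- diag(1, 6)
  Theta[1, 2] <- Theta[2, 1] <- 0.4
  Theta[3, 4] <- Theta[4, 3] <- -0.3
  Sig <- solve(Theta)
  X <- matrix(rnorm(31 * 20 * 6), 31 * 20, 6) %*% chol(Sig)
  covs <- lapply(1:20, function(i) {
    weighted_covariance(X[((i - 1) * 31 + 1):(i * 31), ], rep(1, 31))
  })
  sl <- select_lambda(covs, n_folds = 3)
  at <- function(l) sl$loglik[which.min(abs(sl$grid - l))]
  expect_gte(at(sl$lambda), sl$loglik[1])
  expect_gte(at(sl$lambda), sl$loglik[length(sl$grid)])
  # single-element grid returned as-is; determinism
  expect_equal(select_lambda(covs, grid = 0.2)$lambda, 0.2)
  expect_identical(select_lambda(covs, n_folds = 3)$lambda, sl$lambda)
})

test_that("dynamic FNC stack has the right geometry and static limit", {
  set.seed(46)
  X <- matrix(rnorm(149 * 5), 149, 5) %*% chol(spd_correlation(diag(0.5, 5) + 0.5))
  spec <- make_taper(31, 3)
  d <- compute_dfnc(X, spec = spec, lambda = 0.1)
  expect_equal(nrow(d$pairs), 119)
  expect_equal(ncol(d$pairs), 10)
  expect_equal(dim(d$z), c(119, 5, 5))
  expect_equal(d$z[3, , ], t(d$z[3, , ]))
  expect_equal(diag(d$z[3, , ]), rep(1, 5))
  # single full-length window at lambda = 0 reproduces static FNC
  s <- static_fnc(X)
  d1 <- compute_dfnc(X, spec = make_taper(149, 3), lambda = 0)
  expect_lt(max(abs(s$pairs - d1$pairs[1, ])), 0.02)
})

test_that("windowed variance distinguishes stationary from switching data", {
  set.seed(47)
  spec <- make_taper(31, 3)
  R1 <- spd_correlation(diag(0.4, 4) + 0.6)
  stat_X <- matrix(rnorm(200 * 4), 200, 4) %*% chol(R1)
  R2 <- spd_correlation(diag(0.4, 4) - 0.2)
  switch_X <- rbind(matrix(rnorm(100 * 4), 100, 4) %*% chol(R1),
                    matrix(rnorm(100 * 4), 100, 4) %*% chol(R2))
  v <- function(X) mean(apply(compute_dfnc(X, spec = spec, lambda = 0.05)$pairs,
                              2, var))
  expect_lt(v(stat_X), v(switch_X))
})

test_that("k-means state clustering recovers planted partitions", {
  set.seed(48)
  ps <- planted_state_windows(3, 12, 100, separation = 10)
  cs <- cluster_states(ps$W, 3, seed = 1)
  tab <- table(cs$cluster, ps$truth)
  expect_equal(sum(apply(tab, 2, max)), 300)  # exact partition recovery
  expect_equal(sum(cs$occupancy), 300)
  # k = 1: centroid is the window mean
  c1 <- cluster_states(ps$W, 1, seed = 1)
  expect_equal(as.numeric(c1$centroids), colMeans(ps$W), tolerance = 1e-10)
  expect_error(cluster_states(ps$W[1:2, ], 3), "fewer windows")
})

test_that("elbow criterion selects the planted state count", {
  set.seed(49)
  ps <- planted_state_windows(4, 10, 120, separation = 8)
  ve <- validity_elbow(ps$W, 2:8, seed = 5)
  expect_equal(ve$k, 4)
  # on unstructured data the index decreases as k grows
  rnd <- matrix(rnorm(300 * 10), 300, 10)
  vr <- validity_elbow(rnd, c(2, 4, 8, 16), seed = 5)
  expect_true(all(diff(vr$index) < 0))
  expect_equal(validity_elbow(ps$W, 5, seed = 1)$k, 5)  # size-1 range
})

test_that("centroid regression matches the normal equations", {
  set.seed(50)
  Cm <- matrix(rnorm(4 * 20), 4, 20)
  W <- matrix(rnorm(30 * 20), 30, 20)
  beta <- centroid_regression(W, Cm)
  X <- t(Cm - rowMeans(Cm))
  Y <- t(W - rowMeans(W))
  brute <- rowMeans(solve(crossprod(X), crossprod(X, Y)))
  expect_equal(beta, brute, tolerance = 1e-8)
  # projection identity on orthogonal, mean-zero centroids
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40), 20, 2))))[, 2:3]
  Co <- t(Q)                          # 2 x 20, orthonormal, zero pair-mean
  w1 <- centroid_regression(matrix(Co[1, ], 1), Co)
  expect_equal(w1, c(1, 0), tolerance = 1e-6)
  wmix <- centroid_regression(matrix(0.5 * Co[1, ] + 0.5 * Co[2, ], 1), Co)
  expect_equal(wmix, c(0.5, 0.5), tolerance = 1e-6)
  expect_warning(centroid_regression(W, rbind(Cm, Cm[1, ])), "rank-deficient")
})

test_that("fold features have length 2k and favor own-group centroids", {
  set.seed(51)
  k <- 2; P <- 12
  psA <- planted_state_windows(k, P, 60, separation = 6)
  psB <- planted_state_windows(k, P, 60, separation = 6)
  mk <- function(ps, n_sub) {
    lapply(seq_len(n_sub), function(i) {
      rows <- sample(nrow(ps$W), 40)
      fake_stack(ps$W[rows, ])
    })
  }
  train <- c(mk(psA, 4), mk(psB, 4))
  names(train) <- sprintf("s%d", 1:8)
  labels <- rep(c("HC", "SZ"), each = 4)
  df <- dfnc_features(train, labels, test_stacks = train[1], k = k, seed = 3)
  expect_equal(ncol(df$train), 2 * k)
  expect_equal(ncol(df$test), 2 * k)
  # HC subjects load mostly on HC centroids (first k positions)
  hc_mass <- rowSums(abs(df$train[1:4, 1:k])) /
    rowSums(abs(df$train[1:4, ]))
  expect_true(all(hc_mass > 0.6))
  # k = 5 with two groups gives 10 features
  ps5 <- planted_state_windows(5, P, 40, separation = 6)
  tr5 <- c(mk(ps5, 3), mk(ps5, 3))
  names(tr5) <- sprintf("t%d", 1:6)
  df5 <- dfnc_features(tr5, rep(c("HC", "SZ"), each = 3), k = 5, seed = 1)
  expect_equal(ncol(df5$train), 10)
})

test_that("state fitting is invariant to training-subject order", {
  set.seed(52)
  ps <- planted_state_windows(2, 8, 80, separation = 8)
  stacks <- lapply(1:6, function(i) fake_stack(ps$W[sample(160, 30), ]))
  names(stacks) <- sprintf("s%d", 1:6)
  labels <- rep(c("HC", "SZ"), 3)
  df1 <- dfnc_features(stacks, labels, k = 2, seed = 9)
  perm <- c(4, 1, 6, 3, 2, 5)
  df2 <- dfnc_features(stacks[perm], labels[perm], k = 2, seed = 9)
  # centroids agree up to within-group state permutation
  match_cost <- function(A, B) {
    apply(abs(cor(t(A), t(B))), 1, max)
  }
  expect_true(all(match_cost(df1$states$HC$centroids,
                             df2$states$HC$centroids) > 0.999))
  expect_true(all(match_cost(df1$states$SZ$centroids,
                             df2$states$SZ$centroids) > 0.999))
})
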