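# Independent oracles and small fixture builders used across the suite.
# Each oracle solves the same problem as the implementation by a different
# method, so agreement is informative.

# ADMM solver for the graphical lasso objective (off-diagonal penalty):
# independent of the package's coordinate-descent path.
admm_glasso <- function(S, lambda, rho = 1, iters = 5000, tol = 1e-10) {
  p <- nrow(S)
  Z <- diag(p); U <- matrix(0, p, p)
  soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)
  for (i in seq_len(iters)) {
    e <- eigen((rho * (Z - U) - S) / rho, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 / rho)) / 2
    Theta <- e$vectors %*% (t(e$vectors) * d)
    Z_old <- Z
    M <- Theta + U
    Z <- soft(M, lambda / rho)
    diag(Z) <- diag(M)
    U <- U + Theta - Z
    if (max(abs(Z - Z_old)) < tol && max(abs(Theta - Z)) < tol) break
  }
  (Z + t(Z)) / 2
}

# Brute-force Benjamini-Hochberg step-up: scan all i explicitly.
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Amari permutation/scale-invariant distance between estimated unmixing
# and true mixing: P = W %*% A.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(P / apply(P, 2, max)) - 1)
  (r + c) / (2 * n * (n - 1))
}

random_spd <- function(p, ridge = 0.5) {
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(ridge, p)
}

# Laplace sources mixed by a random square matrix.
laplace_mixture <- function(n, k) {
  S <- matrix(sample(c(-1, 1), n * k, TRUE) * rexp(n * k), n, k)
  A <- matrix(rnorm(k * k), k, k)
  list(X = S %*% t(A), A = A, S = S)
}

# Small synthetic cohort with a single fMRI-like source.
tiny_cohort <- function(n_per_group = 5, C = 6, T_n = 80, dr = 0,
                        pairs = data.frame(i = 1, j = 2)[0, ],
                        n_states = 1, seed = 1, ...) {
  ep <- if (nrow(pairs) == 0 || dr == 0) {
    data.frame(source = character(0), i = integer(0), j = integer(0),
               dr = numeric(0))
  } else {
    data.frame(source = "fmri", i = pairs$i, j = pairs$j, dr = dr)
  }
  cfg <- simulation_config(n_sz = n_per_group, n_hc = n_per_group,
                           C_fmri = C, C_meg = C, T_fmri = T_n, T_meg = 64,
                           bands = character(0), effect_pairs = ep,
                           n_states = n_states, seed = seed, ...)
  simulate_study(cfg)
}

# Window vectors drawn around k well-separated planted centroids.
# Centroids are mutually orthogonal with equal norms, so all pairwise
# centroid distances equal separation * (per-point spread) * sqrt(2).
planted_state_windows <- function(k, P, n_per_state, separation = 5,
                                  spread = 0.2) {
  Q <- qr.Q(qr(matrix(rnorm(P * k), P, k)))
  centroids <- t(Q) * separation * spread * sqrt(P)
  W <- do.call(rbind, lapply(seq_len(k), function(s) {
    sweep(matrix(rnorm(n_per_state * P, sd = spread), n_per_state, P),
          2, centroids[s, ], "+")
  }))
  list(W = W, centroids = centroids,
       truth = rep(seq_len(k), each = n_per_state))
}

# Fabricate a dynamic-FNC stack from a plain window matrix.
fake_stack <- function(pairs) {
  structure(list(pairs = as.matrix(pairs)), class = "mmfnc_dstack")
}
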