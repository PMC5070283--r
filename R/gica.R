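# Group spatial ICA stage: PCA reductions, infomax with ICASSO-style
# stability selection, dual-regression back-reconstruction, spectral
# component screening. The static/dynamic FNC stages accept externally
# supplied component timecourses directly, so this stage is optional in
# the pipeline.

#' Subject-level PCA reduction
#'
#' Economy-size SVD reduction of one subject's T x V data matrix to R
#' principal components.
#'
#' @param x numeric T x V matrix.
#' @param R number of components to retain (R <= min(T, V)).
#' @return list with `model` (fields `basis` V x R orthonormal,
#'   `variances` non-increasing, `center`, `R`) and `scores` (T x R
#'   reduced data).
#' @export
reduce_subject_pca <- function(x, R) {
  x <- as.matrix(x)
  if (R < 1 || R > min(dim(x))) {
    stop(sprintf("R = %d out of range: must be in 1..min(T, V) = %d", R, min(dim(x))))
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = R, nv = R)
  variances <- sv$d[seq_len(R)]^2 / (nrow(x) - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(R)], R)
  list(model = list(basis = sv$v, variances = variances,
                    center = center, R = R,
                    total_variance = sum(sv$d^2) / (nrow(x) - 1)),
       scores = scores)
}

#' Group-level EM-PCA reduction
#'
#' Expectation-maximization PCA (iterative low-rank factor estimation) of
#' stacked reduced data, used at the group reduction stage where a dense
#' decomposition of the full stack would be memory-heavy. The converged
#' subspace agrees with direct PCA; the returned basis is rotated to
#' principal axes with non-increasing variances.
#'
#' @param x stacked data matrix (rows = stacked samples, columns = dims).
#' @param R components to retain.
#' @param tol convergence tolerance on the subspace change.
#' @param max_iter maximum EM iterations.
#' @param seed seed for the random subspace initialization.
#' @return A PCA model list (`basis`, `variances`, `center`, `R`) plus
#'   `scores`, `iterations`, `converged`.
#' @export
reduce_group_empca <- function(x, R, tol = 1e-10, max_iter = 1000, seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (R < 1 || R > min(dim(x))) stop("R out of range")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  W <- with_seed(seed, matrix(stats::rnorm(p * R), p, R))
  prev <- qr.Q(qr(W))
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # E-step: latent scores Z given W; M-step: update W
    Z <- xc %*% W %*% solve(crossprod(W))          # n x R
    W <- crossprod(xc, Z) %*% solve(crossprod(Z))  # p x R
    Q <- qr.Q(qr(W))
    delta <- principal_angle(prev, Q)
    prev <- Q
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("EM-PCA did not converge in %d iterations; returning best iterate",
                    max_iter))
  }
  # rotate the converged subspace to principal axes
  proj <- xc %*% Q                       # n x R
  e <- eigen(stats::cov(proj), symmetric = TRUE)
  basis <- Q %*% e$vectors
  scores <- xc %*% basis
  list(basis = basis, variances = e$values, center = center, R = R,
       scores = scores, iterations = it, converged = converged,
       total_variance = sum(apply(xc, 2, stats::var)))
}

#' Whiten data to R dimensions
#'
#' PCA-whitening: projects centered data onto the leading R principal axes
#' and scales each to unit variance, so the whitened covariance is the
#' identity.
#'
#' @param x data matrix (rows = samples).
#' @param R retained dimension.
#' @return list with `white` (n x R), `dewhiten` (R x p back-projection),
#'   `center`.
#' @export
whiten <- function(x, R = ncol(x)) {
  red <- reduce_subject_pca(x, R)
  sd <- sqrt(red$model$variances)
  if (any(sd <= 0)) stop("rank-deficient data: cannot whiten to R dimensions")
  white <- sweep(red$scores, 2, sd, "/")
  list(white = white, basis = red$model$basis, sd = sd, center = red$model$center)
}

#' Infomax ICA
#'
#' Natural-gradient infomax with the logistic nonlinearity on whitened
#' data. The learning rate anneals (x 0.9) whenever the weight update
#' blows up, and iteration stops when the between-pass weight change
#' drops below `tol`.
#'
#' @param x whitened data matrix (n samples x C_ic dims; covariance ~ I).
#' @param seed seed for the random orthogonal initialization and sample
#'   permutations.
#' @param lr initial learning rate.
#' @param tol stopping tolerance on the weight change.
#' @param max_pass maximum passes over the data.
#' @param block minibatch size.
#' @param max_restarts random restarts allowed after divergence.
#' @return list of class `mmfnc_ica`: `unmixing` (C_ic x C_ic), `sources`
#'   (n x C_ic), `seed`, `iterations`, `lr_trace`.
#' @export
run_infomax <- function(x, seed = 1, lr = 0.01, tol = 1e-7, max_pass = 512,
                        block = NULL, max_restarts = 5) {
  x <- as.matrix(x)
  n <- nrow(x); C <- ncol(x)
  if (is.null(block)) block <- min(n, max(32L, floor(sqrt(n))))
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      W <- qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
      lr_now <- lr
      lr_trace <- numeric(0)
      diverged <- FALSE
      it <- 0
      for (pass in seq_len(max_pass)) {
        it <- pass
        W_old <- W
        perm <- sample.int(n)
        starts <- seq(1, n, by = block)
        for (s in starts) {
          idx <- perm[s:min(s + block - 1, n)]
          u <- x[idx, , drop = FALSE] %*% t(W)
          y <- 1 / (1 + exp(-u))
          grad <- (diag(length(idx), C) + crossprod(1 - 2 * y, u)) %*% W
          W <- W + (lr_now / length(idx)) * grad
          if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
            lr_now <- lr_now * 0.9
            W <- W_old
            diverged <- TRUE
            break
          }
        }
        lr_trace <- c(lr_trace, lr_now)
        dW <- max(abs(W - W_old))
        if (diverged) {
          diverged <- FALSE
          if (lr_now < 1e-12) break
          next
        }
        if (dW < tol) {
          return(structure(list(unmixing = W, sources = x %*% t(W),
                                seed = seed, iterations = it,
                                lr_trace = lr_trace, converged = TRUE),
                           class = "mmfnc_ica"))
        }
      }
      if (all(is.finite(W))) {
        return(structure(list(unmixing = W, sources = x %*% t(W),
                              seed = seed, iterations = it,
                              lr_trace = lr_trace, converged = FALSE),
                         class = "mmfnc_ica"))
      }
    }
    stop("infomax diverged after maximum restarts")
  })
}

#' ICASSO-style stability selection
#'
#' Runs infomax `n_runs` times from different random starts, pools all
#' estimated components, clusters them by absolute Pearson correlation
#' (agglomerative average linkage cut at `C_ic` clusters), scores each
#' cluster with the quality index (mean intra-cluster similarity minus
#' mean extra-cluster similarity), and returns the single run whose
#' components best match the cluster centrotypes.
#'
#' @param x whitened data (n x C_ic).
#' @param C_ic number of components.
#' @param n_runs ICA repetitions (>= 2).
#' @param seed base seed; run r uses seed + r.
#' @param ... passed to [run_infomax()].
#' @return list with `report` (per-component `quality` in \[-1, 1\],
#'   `cluster` assignment of run-wise components, `chosen_run`) and
#'   `decomposition` (the chosen run's `mmfnc_ica`).
#' @export
icasso_stability <- function(x, C_ic = ncol(x), n_runs = 20, seed = 1, ...) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  runs <- lapply(seq_len(n_runs), function(r) run_infomax(x, seed = seed + r, ...))
  comps <- do.call(cbind, lapply(runs, function(r) r$sources)) # n x (runs*C_ic)
  run_of <- rep(seq_len(n_runs), each = C_ic)
  sim <- abs(stats::cor(comps))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = C_ic)
  if (length(unique(cl)) < C_ic) {
    stop(sprintf("degenerate clustering: only %d distinct clusters for %d components",
                 length(unique(cl)), C_ic))
  }
  quality <- vapply(seq_len(C_ic), function(k) {
    inside <- which(cl == k)
    outside <- which(cl != k)
    intra <- if (length(inside) > 1) {
      mean(sim[inside, inside][upper.tri(matrix(0, length(inside), length(inside)))])
    } else 1
    extra <- mean(sim[inside, outside, drop = FALSE])
    intra - extra
  }, 0)
  # centrotype of each cluster: member with max total intra-cluster similarity
  centro <- vapply(seq_len(C_ic), function(k) {
    inside <- which(cl == k)
    inside[which.max(rowSums(sim[inside, inside, drop = FALSE]))]
  }, 0L)
  # chosen run: greedy-match its components to centrotypes, max mean similarity
  run_score <- vapply(seq_len(n_runs), function(r) {
    cols <- which(run_of == r)
    mean(apply(sim[centro, cols, drop = FALSE], 1, max))
  }, 0)
  chosen <- which.max(run_score)
  list(report = list(quality = quality, cluster = cl, run = run_of,
                     centrotypes = centro, chosen_run = chosen,
                     run_scores = run_score),
       decomposition = runs[[chosen]])
}

#' Back-reconstruct subject timecourses by dual regression
#'
#' Given group-level spatial maps (components x features) and a subject's
#' T x V data, recovers subject-specific component timecourses as the
#' least-squares projection of the data onto the maps.
#'
#' @param maps C_ic x V group map matrix.
#' @param x subject T x V data.
#' @return T x C_ic subject timecourse matrix.
#' @export
back_reconstruct <- function(maps, x) {
  maps <- as.matrix(maps); x <- as.matrix(x)
  if (ncol(maps) != ncol(x)) stop("maps and data must share the feature dimension")
  G <- tcrossprod(maps)  # C x C
  qrG <- qr(G)
  if (qrG$rank < nrow(maps)) stop("rank-deficient map matrix")
  t(solve(G, maps %*% t(x)))
}

#' Spectral screening metrics for one component timecourse
#'
#' Computes a Welch-averaged power spectrum and two screening metrics used
#' to flag artifactual components: the low-frequency/high-frequency power
#' ratio (integral of power below 0.10 Hz over the integral between 0.15
#' and 0.25 Hz) and the dynamic range (difference between the peak power
#' and the minimum power at frequencies to the right of the peak, on the
#' unit-total-power scale).
#'
#' @param tc numeric timecourse (length >= 32).
#' @param fs sampling rate in Hz (must cover 0.25 Hz, i.e. fs >= 0.5).
#' @return list with `dynamic_range`, `lf_hf_ratio`, `freq`, `power`.
#' @export
component_spectral_metrics <- function(tc, fs) {
  tc <- as.numeric(tc)
  if (length(tc) < 32) stop("need at least 32 samples for spectral metrics")
  if (fs / 2 < 0.25) {
    stop(sprintf("fs = %g too low: spectrum must cover the 0.15-0.25 Hz band", fs))
  }
  ps <- welch_psd(tc, fs)
  p <- ps$power / sum(ps$power)
  f <- ps$freq
  lf <- sum(p[f < 0.10])
  hf <- sum(p[f >= 0.15 & f <= 0.25])
  lf_hf <- if (hf <= 0) Inf else lf / hf
  pk <- which.max(p)
  dyn <- if (pk == length(p)) 0 else p[pk] - min(p[pk:length(p)])
  list(dynamic_range = dyn, lf_hf_ratio = lf_hf, freq = f, power = p)
}

# Welch periodogram: Hann-windowed overlapping segments, averaged.
welch_psd <- function(x, fs, nseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nseg)) nseg <- max(32L, 2^floor(log2(n / 4)))
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, n - nseg + 1, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(floor(nseg / 2) + 1)]
  }
  power <- acc / (length(starts) * sum(win^2) * fs)
  freq <- (seq_len(floor(nseg / 2) + 1) - 1) * fs / nseg
  list(freq = freq, power = power)
}

#' Rule-based component retention
#'
#' Deterministic replacement for expert visual screening: a component is
#' retained iff its low/high frequency power ratio and dynamic range both
#' reach their thresholds.
#'
#' @param metrics list of per-component metric lists (as returned by
#'   [component_spectral_metrics()]), or a data.frame with columns
#'   `lf_hf_ratio`, `dynamic_range`.
#' @param lf_hf_min threshold on the low/high ratio (default 2: low
#'   frequencies must carry at least twice the high-frequency power).
#' @param dynamic_range_min threshold on the dynamic range (unit-power
#'   scale; default 0.01).
#' @return integer vector of retained component indices.
#' @export
select_components <- function(metrics, lf_hf_min = 2, dynamic_range_min = 0.01) {
  if (is.data.frame(metrics)) {
    lf <- metrics$lf_hf_ratio; dr <- metrics$dynamic_range
  } else {
    lf <- vapply(metrics, function(m) m$lf_hf_ratio, 0)
    dr <- vapply(metrics, function(m) m$dynamic_range, 0)
  }
  which(lf >= lf_hf_min & dr >= dynamic_range_min)
}
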