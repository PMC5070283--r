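#' Tapered sliding-window specification
#'
#' The window is a rectangle of `w` ones convolved with a unit-sum
#' Gaussian kernel of width `sigma` samples (truncated at +-3 sigma),
#' center-cropped back to length `w` and renormalized to sum `w`. With
#' sigma -> 0 the taper degenerates to the plain rectangular window.
#'
#' @param w window width in samples (default 31).
#' @param sigma Gaussian taper width in samples (default 3).
#' @param step window step in samples (default 1).
#' @return Object of class `mmfnc_window`: `w`, `step`, `sigma`,
#'   `weights` (length w, symmetric, max at center, sum w).
#' @export
make_taper <- function(w = 31, sigma = 3, step = 1) {
  if (w < 3) stop("window width must be >= 3")
  if (sigma < 0) stop("sigma must be >= 0")
  if (step < 1) stop("step must be >= 1")
  if (sigma == 0) {
    weights <- rep(1, w)
  } else {
    h <- max(1L, ceiling(3 * sigma))
    g <- stats::dnorm(-h:h, sd = sigma)
    g <- g / sum(g)
    full <- stats::convolve(c(rep(0, h), rep(1, w), rep(0, h)), rev(g), type = "open")
    # full length = (w + 2h) + 2h - 1; center-crop to w
    off <- (length(full) - w) %/% 2
    weights <- full[(off + 1):(off + w)]
    weights <- (weights + rev(weights)) / 2  # enforce exact symmetry
    weights <- weights * (w / sum(weights))
    if ((max(weights) - min(weights)) / max(weights) < 0.05) {
      warning("taper is near-flat: sigma is large relative to the window")
    }
  }
  structure(list(w = as.integer(w), step = as.integer(step), sigma = sigma,
                 weights = weights), class = "mmfnc_window")
}

#' Enumerate sliding windows
#'
#' @param T_n series length in samples.
#' @param spec an [make_taper()] window specification.
#' @return data.frame with `start` (1-based) and `end`; exactly
#'   `floor((T - w)/step) + 1` full windows, no partial windows.
#' @export
sliding_windows <- function(T_n, spec) {
  stopifnot(inherits(spec, "mmfnc_window"))
  if (T_n < spec$w) {
    stop(sprintf("series length %d shorter than window width %d", T_n, spec$w))
  }
  n <- (T_n - spec$w) %/% spec$step + 1L
  start <- 1L + (seq_len(n) - 1L) * spec$step
  data.frame(start = start, end = start + spec$w - 1L)
}

#' Weighted covariance of a windowed segment
#'
#' Weighted mean removed; normalization by the weight sum (so a one-hot
#' weight vector gives the zero matrix).
#'
#' @param x w x C data segment.
#' @param weights non-negative weights, length w, not all zero.
#' @return C x C symmetric PSD covariance matrix.
#' @export
weighted_covariance <- function(x, weights) {
  x <- as.matrix(x)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(x)) stop("weights length must match rows of x")
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  nw <- weights / sum(weights)
  mu <- colSums(x * nw)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc * sqrt(nw))
  S <- (S + t(S)) / 2
  eff_n <- 1 / sum(nw^2)
  if (eff_n > 1 + 1e-12 && any(diag(S) <= 0)) {
    stop(sprintf("zero-variance column in window: %s",
                 paste(which(diag(S) <= 0), collapse = ", ")))
  }
  S
}

#' Graphical LASSO sparse precision estimation
#'
#' Block coordinate-descent solver (lasso on each column of the precision
#' matrix) maximizing `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1,off`
#' (off-diagonal penalty only). Returns both the precision estimate and
#' its inverse, the regularized covariance (ICOV-derived covariance).
#'
#' @param S symmetric PSD covariance matrix (a 1e-8 ridge is added if
#'   needed).
#' @param lambda L1 penalty, >= 0.
#' @param tol convergence tolerance on the maximum parameter change.
#' @param max_sweeps maximum full sweeps over columns.
#' @return list: `theta` (SPD precision), `sigma` (its inverse),
#'   `lambda`, `sweeps`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-6, max_sweeps = 500) {
  S <- as.matrix(S)
  C <- nrow(S)
  if (lambda < 0) stop("lambda must be >= 0")
  S <- (S + t(S)) / 2
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) S <- S + diag(1e-8 - min(ev_min, 0) + 1e-10, C)
  if (lambda == 0) {
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    return(list(theta = theta, sigma = S, lambda = lambda,
                sweeps = 0L, converged = TRUE))
  }
  W <- S
  B <- matrix(0, C - 1, C)   # lasso coefficients per column
  converged <- FALSE
  sweeps <- 0L
  for (sweep_i in seq_len(max_sweeps)) {
    sweeps <- sweep_i
    W_old <- W
    for (j in seq_len(C)) {
      idx <- setdiff(seq_len(C), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, lambda, beta = B[, j], tol = tol * 0.1)
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("graphical lasso did not converge in %d sweeps at lambda = %g",
                 max_sweeps, lambda))
  }
  theta <- matrix(0, C, C)
  for (j in seq_len(C)) {
    idx <- setdiff(seq_len(C), j)
    denom <- W[j, j] - sum(W[idx, j] * B[, j])
    theta[j, j] <- 1 / denom
    theta[idx, j] <- -B[, j] * theta[j, j]
  }
  theta <- (theta + t(theta)) / 2
  list(theta = theta, sigma = W, lambda = lambda,
       sweeps = sweeps, converged = converged)
}

# Coordinate-descent lasso for 1/2 b'Qb - b's + lambda|b|_1.
lasso_cd <- function(Q, s, lambda, beta = NULL, tol = 1e-8, max_iter = 1000) {
  p <- length(s)
  if (is.null(beta)) beta <- rep(0, p)
  qd <- diag(Q)
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (k in seq_len(p)) {
      r <- s[k] - sum(Q[k, ] * beta) + qd[k] * beta[k]
      bnew <- sign(r) * max(abs(r) - lambda, 0) / qd[k]
      d <- abs(bnew - beta[k])
      if (d > delta_max) delta_max <- d
      beta[k] <- bnew
    }
    if (delta_max < tol) break
  }
  beta
}

#' Per-subject penalty selection by cross-validated likelihood
#'
#' Splits a subject's windows into contiguous folds; for each candidate
#' lambda, fits the graphical lasso on the pooled training-fold covariance
#' and evaluates the Gaussian log-likelihood
#' `log det(Theta) - tr(S_test Theta)` on the held-out pooled covariance.
#' Returns the lambda maximizing the mean held-out log-likelihood (ties
#' broken toward the larger lambda).
#'
#' @param covs list of per-window covariance matrices.
#' @param grid candidate lambdas (default 10 points log-spaced in
#'   \[0.01, 1\]).
#' @param n_folds contiguous folds (default 3).
#' @return list: `lambda` (the selected value), `loglik` (mean held-out
#'   log-likelihood per grid point), `grid`.
#' @export
select_lambda <- function(covs, grid = default_lambda_grid(), n_folds = 3) {
  if (length(grid) == 0) stop("empty lambda grid")
  if (length(grid) == 1) {
    return(list(lambda = grid, loglik = NA_real_, grid = grid))
  }
  n <- length(covs)
  if (n_folds < 2) stop("need at least 2 folds")
  n_folds <- min(n_folds, n)
  fold_id <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  mean_cov <- function(ix) Reduce(`+`, covs[ix]) / length(ix)
  ll <- vapply(grid, function(lam) {
    fold_ll <- vapply(seq_len(n_folds), function(f) {
      tr_ix <- which(fold_id != f)
      te_ix <- which(fold_id == f)
      fit <- tryCatch(graphical_lasso(mean_cov(tr_ix), lam),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      S_te <- mean_cov(te_ix)
      as.numeric(determinant(fit$theta, logarithm = TRUE)$modulus) -
        sum(S_te * fit$theta)
    }, 0)
    mean(fold_ll)
  }, 0)
  if (all(is.na(ll))) stop("all graphical lasso fits failed across the grid")
  best <- max(ll, na.rm = TRUE)
  lambda <- max(grid[!is.na(ll) & ll >= best - 1e-12])
  list(lambda = lambda, loglik = ll, grid = grid)
}

#' Default penalty grid: 10 points log-spaced in [0.01, 1]
#' @return numeric vector of length 10.
#' @export
default_lambda_grid <- function() exp(seq(log(0.01), log(1), length.out = 10))

#' Dynamic FNC stack for one subject
#'
#' Despikes the component timecourses, slides the tapered window along
#' them, and for each window estimates a weighted covariance, regularizes
#' it through the graphical lasso at the subject's penalty (cross-validated
#' unless given), converts the regularized covariance to correlation, and
#' Fisher-z transforms it.
#'
#' @param tcs `mmfnc_tcs` object or T x C matrix.
#' @param spec window specification from [make_taper()].
#' @param lambda `"cv"` (default) for per-subject cross-validation, or a
#'   fixed non-negative number.
#' @param grid,n_folds penalty-selection settings (see [select_lambda()]).
#' @param despike despike first (default TRUE).
#' @return Object of class `mmfnc_dstack`: `pairs` (N windows x P pair
#'   matrix of Fisher-z values), `z` (N x C x C array), `starts`,
#'   `lambda`, provenance.
#' @export
compute_dfnc <- function(tcs, spec = make_taper(), lambda = "cv",
                         grid = default_lambda_grid(), n_folds = 3,
                         despike = TRUE) {
  if (inherits(tcs, "mmfnc_tcs")) {
    X <- tcs$data
    prov <- tcs[c("subject_id", "group", "modality", "band")]
  } else {
    X <- as.matrix(tcs)
    prov <- list(subject_id = NA_character_, group = NA_character_,
                 modality = NA_character_, band = NA_character_)
  }
  if (despike) X <- apply(X, 2, despike)
  C <- ncol(X)
  win <- sliding_windows(nrow(X), spec)
  covs <- lapply(seq_len(nrow(win)), function(i) {
    weighted_covariance(X[win$start[i]:win$end[i], , drop = FALSE], spec$weights)
  })
  if (identical(lambda, "cv")) {
    lambda <- select_lambda(covs, grid = grid, n_folds = n_folds)$lambda
  }
  P <- C * (C - 1) / 2
  pairs <- matrix(0, nrow(win), P)
  zarr <- array(0, dim = c(nrow(win), C, C))
  for (i in seq_len(nrow(win))) {
    fit <- graphical_lasso(covs[[i]], lambda)
    R <- stats::cov2cor(fit$sigma)
    Z <- fisher_z(R * (1 - diag(C)))
    diag(Z) <- 1
    zarr[i, , ] <- Z
    pairs[i, ] <- vectorize_upper(Z)
  }
  structure(c(list(pairs = pairs, z = zarr, starts = win$start,
                   lambda = lambda, spec = spec), prov),
            class = "mmfnc_dstack")
}

#' @export
print.mmfnc_dstack <- function(x, ...) {
  cat(sprintf("Dynamic FNC stack: %d windows x %d pairs (w = %d, lambda = %.3g)\n",
              nrow(x$pairs), ncol(x$pairs), x$spec$w, x$lambda))
  invisible(x)
}

#' Cluster windowed connectivity into states
#'
#' k-means (Euclidean by default) on window vectors in Fisher-z pair
#' space, with seeded k-means++ initialization and multiple restarts; the
#' solution with the lowest total within-cluster sum of squares is kept.
#' Called once per group on all of that group's training windows.
#'
#' @param windows n_windows x P matrix of window pair vectors.
#' @param k number of states.
#' @param seed RNG seed.
#' @param metric `"euclidean"` (default), `"correlation"` or `"cosine"`;
#'   the non-Euclidean metrics are applied by row-standardizing window
#'   vectors before clustering.
#' @param nstart restarts (default 10).
#' @param group optional group label recorded on the result.
#' @return Object of class `mmfnc_states`: `centroids` (k x P),
#'   `occupancy` (windows per state), `cluster`, `inertia`, `k`, `group`.
#' @export
cluster_states <- function(windows, k, seed = 1, metric = c("euclidean", "correlation", "cosine"),
                           nstart = 10, group = NA_character_) {
  metric <- match.arg(metric)
  W <- as.matrix(windows)
  if (nrow(W) < k) stop("fewer windows than states")
  Wm <- switch(metric,
    euclidean = W,
    correlation = t(scale(t(W))),
    cosine = W / sqrt(rowSums(W^2)))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      init <- kmeanspp_init(Wm, k)
      km <- tryCatch(stats::kmeans(Wm, centers = init, iter.max = 100),
                     error = function(e) NULL)
      if (is.null(km)) next
      if (any(km$size == 0)) {
        # empty cluster: re-seed that centroid at a random window and retry
        empty <- which(km$size == 0)
        init[empty, ] <- Wm[sample.int(nrow(Wm), length(empty)), , drop = FALSE]
        km2 <- tryCatch(stats::kmeans(Wm, centers = init, iter.max = 100),
                        error = function(e) NULL)
        if (!is.null(km2) && !any(km2$size == 0)) km <- km2 else next
        message("cluster_states: re-seeded an empty cluster")
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts")
  centroids <- best$centers
  if (metric != "euclidean") {
    # report centroids in the original pair space (mean of members)
    centroids <- t(vapply(seq_len(k), function(s) colMeans(W[best$cluster == s, , drop = FALSE]),
                          numeric(ncol(W))))
  }
  structure(list(centroids = centroids, occupancy = as.integer(best$size),
                 cluster = best$cluster, inertia = best$tot.withinss,
                 k = as.integer(k), metric = metric, group = group),
            class = "mmfnc_states")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (c_i in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0) {
      j <- sample.int(n, 1)
    } else {
      j <- sample.int(n, 1, prob = probs)
    }
    centers[c_i + 1, ] <- X[j, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c_i + 1, ])^2))
  }
  centers
}

#' @export
print.mmfnc_states <- function(x, ...) {
  cat(sprintf("Connectivity states: k = %d (%s), occupancy %s\n",
              x$k, x$metric, paste(x$occupancy, collapse = "/")))
  invisible(x)
}

#' Elbow selection of the state count
#'
#' For each candidate k the cluster validity index is the ratio of the
#' mean within-cluster distance to the mean between-centroid distance;
#' the selected k* is the elbow, operationalized as the point of maximum
#' curvature (largest discrete second difference) of the index curve.
#'
#' @param windows n x P window matrix.
#' @param k_range candidate k values (increasing).
#' @param seed RNG seed.
#' @return list: `k` (selected), `index` (validity index per candidate),
#'   `k_range`.
#' @export
validity_elbow <- function(windows, k_range, seed = 1) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 1) {
    return(list(k = k_range, index = NA_real_, k_range = k_range))
  }
  W <- as.matrix(windows)
  idx <- vapply(seq_along(k_range), function(m) {
    cs <- cluster_states(W, k_range[m], seed = derive_seed(seed, m))
    within <- mean(sqrt(rowSums((W - cs$centroids[cs$cluster, , drop = FALSE])^2)))
    between <- mean(stats::dist(cs$centroids))
    within / between
  }, 0)
  if (length(k_range) < 3) {
    k_star <- k_range[which.min(idx)]
    return(list(k = k_star, index = idx, k_range = k_range))
  }
  d2 <- idx[seq_len(length(idx) - 2)] - 2 * idx[seq(2, length(idx) - 1)] +
    idx[seq(3, length(idx))]
  if (max(d2) <= 0) {
    warning("validity index has no positive curvature; returning smallest k")
    return(list(k = k_range[1], index = idx, k_range = k_range))
  }
  k_star <- k_range[which.max(d2) + 1]
  list(k = k_star, index = idx, k_range = k_range)
}

#' Centroid-regression beta features
#'
#' For every window, regresses the window's pair vector (mean-centered in
#' pair space) on the design matrix of 2k mean-centered group centroids
#' (no intercept), then averages the per-window coefficients to a single
#' length-2k feature vector.
#'
#' @param stack an `mmfnc_dstack` (or n x P window matrix).
#' @param centroids 2k x P matrix of state centroids (group-A states
#'   first, then group-B).
#' @return numeric feature vector of length 2k.
#' @export
centroid_regression <- function(stack, centroids) {
  W <- if (inherits(stack, "mmfnc_dstack")) stack$pairs else as.matrix(stack)
  Cm <- as.matrix(centroids)
  if (ncol(W) != ncol(Cm)) stop("windows and centroids must share the pair dimension")
  X <- t(Cm - rowMeans(Cm))             # P x 2k design
  Y <- t(W - rowMeans(W))               # P x n
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient centroid design; using ridge fallback")
    XtX <- crossprod(X) + diag(1e-6, ncol(X))
    betas <- solve(XtX, crossprod(X, Y))
  } else {
    betas <- qr.coef(qx, Y)
  }
  rowMeans(betas)
}

#' Dynamic-FNC features for a LOOCV fold
#'
#' Fits per-group connectivity states on the training subjects' windows
#' only, stacks the 2k centroids (HC states first, then SZ), and computes
#' centroid-regression betas for every training and test subject.
#'
#' @param train_stacks named list of `mmfnc_dstack` for training subjects.
#' @param train_labels group labels aligned with `train_stacks`.
#' @param test_stacks named list of stacks to project (may be empty).
#' @param k states per group.
#' @param seed RNG seed.
#' @param metric clustering metric (see [cluster_states()]).
#' @return list: `train` (matrix, training subjects x 2k), `test`
#'   (matrix), `states` (list of the two `mmfnc_states`).
#' @export
dfnc_features <- function(train_stacks, train_labels, test_stacks = list(),
                          k = 5, seed = 1, metric = "euclidean") {
  train_labels <- as.character(train_labels)
  stopifnot(length(train_stacks) == length(train_labels))
  lv <- group_levels()
  states <- lapply(seq_along(lv), function(gi) {
    g <- lv[gi]
    W <- do.call(rbind, lapply(train_stacks[train_labels == g],
                               function(s) s$pairs))
    if (is.null(W) || nrow(W) < k) stop(sprintf("group %s: fewer windows than states", g))
    cluster_states(W, k, seed = derive_seed(seed, gi), metric = metric, group = g)
  })
  names(states) <- lv
  centroids <- rbind(states[[1]]$centroids, states[[2]]$centroids)
  feat <- function(stacks) {
    if (length(stacks) == 0) return(matrix(0, 0, 2 * k))
    t(vapply(stacks, function(s) centroid_regression(s, centroids),
             numeric(2 * k)))
  }
  list(train = feat(train_stacks), test = feat(test_stacks), states = states)
}
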