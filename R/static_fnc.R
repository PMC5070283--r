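#' Despike a timecourse
#'
#' Replaces samples that deviate from a running median (window 5) by more
#' than `c` median absolute deviations with the running median. All other
#' samples are unchanged; a constant series is returned unchanged.
#'
#' @param x numeric series (length >= 5).
#' @param c spike threshold in MAD multiples (default 4).
#' @param window running-median window (odd, default 5).
#' @return The despiked series.
#' @export
despike <- function(x, c = 4, window = 5) {
  x <- as.numeric(x)
  if (length(x) < 5) stop("despike needs at least 5 samples")
  med <- stats::runmed(x, window, endrule = "median")
  resid <- x - med
  s <- stats::mad(resid)
  if (s == 0) return(x)
  out <- x
  spikes <- abs(resid) > c * s
  out[spikes] <- med[spikes]
  out
}

#' Static functional network connectivity
#'
#' Pairwise Pearson correlation among all component timecourses over their
#' full length (after despiking). With `max_lag > 0`, each pair's value is
#' the signed correlation of maximal absolute value over lags -L..L.
#'
#' @param tcs an `mmfnc_tcs` object (or plain T x C matrix).
#' @param max_lag maximum lag in samples (default 0 = zero-lag).
#' @param despike despike timecourses first (default TRUE).
#' @return Object of class `mmfnc_static`: `corr` (C x C, unit diagonal),
#'   `z` (Fisher-z matrix, zero diagonal), `pairs` (z values in
#'   [pair_index()] order), provenance fields.
#' @export
static_fnc <- function(tcs, max_lag = 0, despike = TRUE) {
  if (inherits(tcs, "mmfnc_tcs")) {
    X <- tcs$data
    prov <- tcs[c("subject_id", "group", "modality", "band")]
  } else {
    X <- as.matrix(tcs)
    prov <- list(subject_id = NA_character_, group = NA_character_,
                 modality = NA_character_, band = NA_character_)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance component: %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  if (despike) X <- apply(X, 2, despike)
  R <- stats::cor(X)
  if (max_lag > 0) {
    C <- ncol(X)
    pi <- pair_index(C)
    for (p in seq_len(nrow(pi))) {
      r <- lagged_correlations(X[, pi$i[p]], X[, pi$j[p]], max_lag)
      best <- r[which.max(abs(r))]
      R[pi$i[p], pi$j[p]] <- best
      R[pi$j[p], pi$i[p]] <- best
    }
  }
  Z <- fisher_z(R * (1 - diag(ncol(R))))  # zero diagonal before transform
  diag(Z) <- 0
  structure(c(list(corr = R, z = Z, pairs = vectorize_upper(Z),
                   max_lag = max_lag), prov),
            class = "mmfnc_static")
}

lagged_correlations <- function(x, y, L) {
  Tn <- length(x)
  vapply(-L:L, function(l) {
    if (l >= 0) stats::cor(x[1:(Tn - l)], y[(1 + l):Tn])
    else stats::cor(x[(1 - l):Tn], y[1:(Tn + l)])
  }, 0)
}

#' @export
print.mmfnc_static <- function(x, ...) {
  cat(sprintf("Static FNC: %d components, %d pairs (%s%s)\n",
              ncol(x$corr), length(x$pairs), x$modality,
              if (!is.na(x$band) && x$band != "none") paste0("/", x$band) else ""))
  invisible(x)
}

#' Fisher z-transformation of correlations
#'
#' z = arctanh(r), with |r| clipped at 1 - 1e-7 so degenerate inputs do
#' not map to infinity. Strictly increasing in r.
#'
#' @param r correlation value(s), |r| <= 1.
#' @return z value(s), same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  r <- sign(r) * pmin(abs(r), 1 - 1e-7)
  atanh(r)
}

#' Per-pair two-sample group tests
#'
#' Welch (unequal-variance) two-sample t-test of each connectivity pair
#' between the two groups, with two-sided p-values and Benjamini-Hochberg
#' adjusted q-values. Pairs with identical values in both groups get
#' t = 0, p = 1.
#'
#' @param z subjects x pairs matrix of Fisher-z connectivity features.
#' @param labels group labels ("HC"/"SZ"), length = nrow(z).
#' @param q FDR level used to flag selected pairs (default 0.05).
#' @return data.frame (class `mmfnc_pairtest`): columns `pair`, `t`, `p`,
#'   `q`, `selected`.
#' @export
pairwise_group_test <- function(z, labels, q = 0.05) {
  z <- as.matrix(z)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(z))
  g1 <- z[labels == group_levels()[1], , drop = FALSE]
  g2 <- z[labels == group_levels()[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate pairs: zero variance in both groups
  degen <- se2 == 0
  t[degen & (m1 == m2)] <- 0
  p[degen & (m1 == m2)] <- 1
  t[degen & (m1 != m2)] <- Inf * sign(m1 - m2)[degen & (m1 != m2)]
  p[degen & (m1 != m2)] <- 0
  adj <- bh_fdr(p, q)
  structure(data.frame(pair = seq_len(ncol(z)), t = t, p = p,
                       q = adj$q, selected = adj$reject),
            class = c("mmfnc_pairtest", "data.frame"))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: reject all hypotheses with sorted p-value
#' p_(i) <= (i/m) q up to the largest such i. Adjusted q-values come from
#' [stats::p.adjust()] with method "BH".
#'
#' @param p vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `q` (adjusted values) and `reject` (logical flags).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(q = adj, reject = adj <= q)
}

#' Select static connectivity features on a training fold
#'
#' Runs the per-pair group test on the training subjects only and returns
#' the pairs passing BH-FDR at level `q`. If no pair passes, falls back to
#' the single best pair by p-value (with a warning), so downstream
#' classifiers always receive at least one feature.
#'
#' @param z training subjects x pairs Fisher-z feature matrix.
#' @param labels training group labels.
#' @param q FDR level.
#' @return list with `pairs` (selected pair indices), `tests`
#'   (full `mmfnc_pairtest` table), `fallback` (logical).
#' @export
select_static_features <- function(z, labels, q = 0.05) {
  tests <- pairwise_group_test(z, labels, q = q)
  sel <- tests$pair[tests$selected]
  fallback <- FALSE
  if (length(sel) == 0) {
    warning("no pair passed FDR selection; falling back to top-1 pair by p-value")
    sel <- tests$pair[which.min(tests$p)]
    fallback <- TRUE
  }
  list(pairs = sel, tests = tests, fallback = fallback)
}
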