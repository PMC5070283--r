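#' Leave-one-out cross-validation folds
#'
#' One fold per subject, in subject-id order: the held-out subject is the
#' test case and all remaining subjects form the training set.
#'
#' @param ids subject identifiers.
#' @param labels group labels aligned with `ids`.
#' @return list of folds, each with `train` (ids) and `test` (one id).
#' @export
loocv_folds <- function(ids, labels) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) < 3) stop("need at least 3 subjects for LOOCV")
  if (length(unique(labels)) < 2) stop("single-class cohort: both groups required")
  lapply(seq_along(ids), function(i) {
    list(train = ids[-i], test = ids[i])
  })
}

#' Classifier specification
#'
#' @param kind `"ldc"` (linear discriminant with shrinkage), `"nbc"`
#'   (Gaussian naive Bayes) or `"nsvm"` (RBF-kernel SVM via
#'   \pkg{e1071}).
#' @param cost,gamma nSVM hyperparameters; `gamma = NULL` uses 1/d on
#'   standardized features.
#' @param shrinkage LDC covariance shrinkage in \[0, 1\] or `"auto"`
#'   (Ledoit-Wolf-style estimate, forced on when features >= training
#'   subjects).
#' @param var_floor NBC per-feature variance floor, as a fraction of the
#'   mean feature variance.
#' @return list of class `mmfnc_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("ldc", "nbc", "nsvm"), cost = 1,
                            gamma = NULL, shrinkage = "auto",
                            var_floor = 1e-3) {
  kind <- match.arg(kind)
  stopifnot(cost > 0, var_floor >= 0)
  structure(list(kind = kind, cost = cost, gamma = gamma,
                 shrinkage = shrinkage, var_floor = var_floor),
            class = "mmfnc_classifier_spec")
}

#' Train on one fold and predict held-out subjects
#'
#' Features are standardized using training-fold statistics only;
#' zero-variance features are dropped with a warning. Confidence is a
#' signed decision value (positive toward "SZ"); exact ties resolve to the
#' first class in the fixed order (HC).
#'
#' @param spec a [classifier_spec()].
#' @param x_train,y_train training features/labels (>= 2 subjects per
#'   class).
#' @param x_test test feature matrix (rows = subjects).
#' @return data.frame with `label` and `confidence` per test row.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  stopifnot(inherits(spec, "mmfnc_classifier_spec"))
  x_train <- as.matrix(x_train)
  x_test <- matrix(as.matrix(x_test), ncol = ncol(x_train))
  y_train <- factor(as.character(y_train), levels = group_levels())
  if (any(table(y_train) < 2)) stop("need at least 2 training subjects per class")
  if (anyNA(x_train) || anyNA(x_test)) stop("missing values in features")
  keep <- apply(x_train, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
    if (!any(keep)) stop("all features have zero variance")
    x_train <- x_train[, keep, drop = FALSE]
    x_test <- x_test[, keep, drop = FALSE]
  }
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  x_train <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
  x_test <- sweep(sweep(x_test, 2, mu), 2, sdv, "/")
  dec <- switch(spec$kind,
    ldc = predict_ldc(x_train, y_train, x_test, spec$shrinkage),
    nbc = predict_nbc(x_train, y_train, x_test, spec$var_floor),
    nsvm = predict_nsvm(x_train, y_train, x_test, spec$cost, spec$gamma))
  label <- ifelse(dec > 0, group_levels()[2], group_levels()[1])
  data.frame(label = label, confidence = dec, stringsAsFactors = FALSE)
}

# Linear discriminant with optional Ledoit-Wolf-style shrinkage of the
# pooled covariance toward a scaled identity. Returns the signed linear
# decision value (positive = second class).
predict_ldc <- function(x, y, x_new, shrinkage = "auto") {
  lv <- levels(y)
  n <- nrow(x); p <- ncol(x)
  m1 <- colMeans(x[y == lv[1], , drop = FALSE])
  m2 <- colMeans(x[y == lv[2], , drop = FALSE])
  xc <- x
  xc[y == lv[1], ] <- sweep(x[y == lv[1], , drop = FALSE], 2, m1)
  xc[y == lv[2], ] <- sweep(x[y == lv[2], , drop = FALSE], 2, m2)
  S <- crossprod(xc) / (n - 2)
  delta <- if (identical(shrinkage, "auto")) {
    if (p >= min(table(y)) || rcond_sym(S) < 1e-8) ledoit_wolf_delta(xc, S) else 0
  } else shrinkage
  target <- diag(mean(diag(S)), p)
  S <- (1 - delta) * S + delta * target
  w <- solve(S, m2 - m1)
  b <- -0.5 * sum(w * (m1 + m2)) + log(mean(y == lv[2]) / mean(y == lv[1]))
  drop(x_new %*% w + b)
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# Ledoit-Wolf shrinkage intensity toward the scaled identity target,
# estimated from the centered data.
ledoit_wolf_delta <- function(xc, S) {
  n <- nrow(xc); p <- ncol(xc)
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- b2 / n^2
  min(1, max(0, b2 / d2))
}

# Gaussian naive Bayes with a variance floor; returns the log-posterior
# difference (class 2 minus class 1).
predict_nbc <- function(x, y, x_new, var_floor) {
  lv <- levels(y)
  stats_for <- function(g) {
    xg <- x[y == g, , drop = FALSE]
    list(mu = colMeans(xg), v = apply(xg, 2, stats::var), prior = mean(y == g))
  }
  s1 <- stats_for(lv[1]); s2 <- stats_for(lv[2])
  floor_v <- var_floor * mean(c(s1$v, s2$v)) + 1e-12
  s1$v <- pmax(s1$v, floor_v); s2$v <- pmax(s2$v, floor_v)
  ll <- function(s) {
    apply(x_new, 1, function(r) {
      sum(stats::dnorm(r, s$mu, sqrt(s$v), log = TRUE)) + log(s$prior)
    })
  }
  ll(s2) - ll(s1)
}

# RBF-kernel soft-margin SVM (e1071); decision value signed toward the
# second class.
predict_nsvm <- function(x, y, x_new, cost, gamma) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, x_new, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  dv <- drop(dvm)
  # column name "A/B": a positive decision value votes for class A
  pos_class <- strsplit(colnames(dvm)[1], "/", fixed = TRUE)[[1]][1]
  if (pos_class == levels(y)[1]) dv <- -dv  # orient positive toward SZ
  dv
}

#' Run the full LOOCV classification pipeline
#'
#' Computes per-subject connectivity features once (static FNC pair
#' vectors, or dynamic FNC window stacks with per-subject penalties), then
#' runs leave-one-out cross-validation with strict fold hygiene: static
#' feature selection and dynamic state centroids are fit on the 90-subject
#' (in general n-1) training fold only, and the held-out subject is
#' projected onto them.
#'
#' @param dataset an `mmfnc_study`.
#' @param mode `"static"` or `"dynamic"`.
#' @param sources sources to analyse: a character vector of single sources
#'   and/or a list whose elements are character vectors (feature
#'   concatenation across the named sources, e.g. `c("fmri", "delta")`).
#' @param classifiers classifier kinds (default all three).
#' @param q static-mode FDR level.
#' @param max_lag static-mode maximum lag in samples.
#' @param k dynamic-mode states per group.
#' @param spec dynamic-mode window specification.
#' @param lambda dynamic-mode penalty policy (`"cv"` or fixed number).
#' @param grid,n_folds dynamic-mode penalty-selection settings.
#' @param seed master seed; per-fold seeds are derived by fixed offsets.
#' @param specs optional named list of [classifier_spec()] overrides.
#' @return Object of class `mmfnc_loocv`: `predictions` (long data.frame
#'   with subject, truth, source, classifier, predicted, confidence),
#'   `accuracy` (per source x classifier plus the mean/sd across
#'   classifiers), `selected_features` (static mode: per-fold selected
#'   pairs), `mode`, `source_names`, `classifiers`.
#' @export
run_pipeline_loocv <- function(dataset, mode = c("static", "dynamic"),
                               sources = NULL,
                               classifiers = c("ldc", "nbc", "nsvm"),
                               q = 0.05, max_lag = 0,
                               k = 5, spec = make_taper(),
                               lambda = "cv", grid = default_lambda_grid(),
                               n_folds = 3, seed = 1, specs = NULL) {
  stopifnot(inherits(dataset, "mmfnc_study"))
  mode <- match.arg(mode)
  if (is.null(sources)) sources <- as.list(ordered_sources(dataset$sources))
  if (is.character(sources)) sources <- as.list(sources)
  source_names <- vapply(sources, paste, "", collapse = "+")
  ids <- names(dataset$subjects)
  labels <- dataset$groups[ids]
  singles <- unique(unlist(sources))
  if (!all(singles %in% dataset$sources)) {
    stop(sprintf("unknown source(s): %s",
                 paste(setdiff(singles, dataset$sources), collapse = ", ")))
  }
  if (is.null(specs)) {
    specs <- lapply(classifiers, function(kind) classifier_spec(kind))
    names(specs) <- classifiers
  }

  # Per-subject per-source representations, computed once.
  reps <- lapply(singles, function(src) {
    lapply(dataset$subjects, function(s) {
      if (mode == "static") {
        static_fnc(s$tcs[[src]], max_lag = max_lag)$pairs
      } else {
        compute_dfnc(s$tcs[[src]], spec = spec, lambda = lambda,
                     grid = grid, n_folds = n_folds)
      }
    })
  })
  names(reps) <- singles

  folds <- loocv_folds(ids, labels)
  pred_rows <- list()
  sel_feats <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tr <- fold$train; te <- fold$test
    for (si in seq_along(sources)) {
      members <- sources[[si]]
      tr_feat <- NULL; te_feat <- NULL
      sel_by_member <- list()
      for (src in members) {
        if (mode == "static") {
          Z <- do.call(rbind, reps[[src]][tr])
          sel <- select_static_features(Z, labels[tr], q = q)
          sel_by_member[[src]] <- sel$pairs
          tr_m <- Z[, sel$pairs, drop = FALSE]
          te_m <- matrix(reps[[src]][[te]][sel$pairs], nrow = 1)
        } else {
          df <- dfnc_features(reps[[src]][tr], labels[tr],
                              test_stacks = reps[[src]][te],
                              k = k, seed = derive_seed(seed, f * 100 + si))
          tr_m <- df$train
          te_m <- df$test
        }
        tr_feat <- if (is.null(tr_feat)) tr_m else cbind(tr_feat, tr_m)
        te_feat <- if (is.null(te_feat)) te_m else cbind(te_feat, te_m)
      }
      if (mode == "static") {
        sel_feats[[source_names[si]]][[te]] <- sel_by_member
      }
      for (cl in classifiers) {
        pr <- fit_predict(specs[[cl]], tr_feat, labels[tr], te_feat)
        pred_rows[[length(pred_rows) + 1]] <- data.frame(
          subject = te, truth = unname(labels[te]),
          source = source_names[si], classifier = cl,
          predicted = pr$label, confidence = pr$confidence,
          stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- do.call(rbind, pred_rows)
  accuracy <- accuracy_table(predictions)
  structure(list(predictions = predictions, accuracy = accuracy,
                 selected_features = sel_feats, mode = mode,
                 source_names = source_names, classifiers = classifiers,
                 seed = seed,
                 label = paste0(mode, ":", paste(source_names, collapse = ","))),
            class = "mmfnc_loocv")
}

# Accuracy per source x classifier, plus Average (mean and sd across
# classifiers) per source.
accuracy_table <- function(predictions) {
  agg <- stats::aggregate(correct ~ source + classifier,
                          data = transform(predictions,
                                           correct = predicted == truth),
                          FUN = mean)
  names(agg)[3] <- "accuracy"
  avg <- do.call(rbind, lapply(split(agg, agg$source), function(d) {
    data.frame(source = d$source[1], classifier = "average",
               accuracy = mean(d$accuracy), sd = stats::sd(d$accuracy))
  }))
  agg$sd <- NA_real_
  rbind(agg, avg)
}

#' @export
print.mmfnc_loocv <- function(x, ...) {
  cat(sprintf("LOOCV %s-FNC classification: %d subjects, sources: %s\n",
              x$mode, length(unique(x$predictions$subject)),
              paste(x$source_names, collapse = ", ")))
  print(summary(x))
  invisible(x)
}

#' @export
summary.mmfnc_loocv <- function(object, ...) {
  acc <- object$accuracy
  wide <- stats::reshape(acc[, c("source", "classifier", "accuracy")],
                         idvar = "classifier", timevar = "source",
                         direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[, -1] <- round(wide[, -1, drop = FALSE] * 100, 2)
  wide
}
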