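#' Simulation configuration for a synthetic two-group cohort
#'
#' Defines the study conditions of the synthetic cohort: 91 subjects
#' (46 SZ / 45 HC) by default, an fMRI source (T = 149 samples at 0.5 Hz,
#' C = 38 components) and five MEG envelope bands (T = 300 at 1 Hz,
#' C = 32), with planted static group differences in a subset of
#' connectivity pairs and Markov-switching connectivity states driving the
#' dynamics. By default group differences are planted in fMRI, delta,
#' alpha and beta — and none in theta and gamma — mirroring the band
#' pattern the pipeline is designed to detect.
#'
#' @param n_sz,n_hc subjects per group.
#' @param C_fmri,C_meg components per modality.
#' @param T_fmri,T_meg samples per modality.
#' @param bands MEG band names to simulate.
#' @param effect_pairs data.frame with columns `source` (`"fmri"` or a band
#'   name), `i`, `j` (component pair, i < j) and `dr` (signed correlation
#'   difference planted in the SZ group). Defaults to
#'   [default_effect_pairs()].
#' @param n_states Markov connectivity states per group.
#' @param dwell state dwell (stay) probability in (0, 1).
#' @param static_weight share of variance carried by the stationary
#'   (static) component vs the switching states, in \[0, 1\].
#' @param smooth_fmri,smooth_meg exponential low-pass coefficient in
#'   \[0, 1); higher = smoother. fMRI default mimics hemodynamic
#'   sluggishness; MEG envelopes are smoothed more lightly.
#' @param base_strength magnitude of the shared baseline correlation
#'   structure.
#' @param state_strength magnitude of per-state covariance perturbations
#'   (state separation).
#' @param seed master seed.
#' @return An object of class `mmfnc_sim_config` (a validated list).
#' @export
simulation_config <- function(n_sz = 46, n_hc = 45,
                              C_fmri = 38, C_meg = 32,
                              T_fmri = 149, T_meg = 300,
                              bands = c("delta", "theta", "alpha", "beta", "gamma"),
                              effect_pairs = NULL,
                              n_states = 5, dwell = 0.9,
                              static_weight = 0.5,
                              smooth_fmri = 0.6, smooth_meg = 0.3,
                              base_strength = 0.25, state_strength = 0.6,
                              seed = 1L) {
  stopifnot(n_sz >= 1, n_hc >= 1, C_fmri >= 2, C_meg >= 2,
            T_fmri >= 2, T_meg >= 2, n_states >= 1)
  if (!(dwell > 0 && dwell <= 1)) stop("dwell must be in (0, 1]")
  if (static_weight < 0 || static_weight > 1) stop("static_weight must be in [0, 1]")
  if (smooth_fmri < 0 || smooth_fmri >= 1 || smooth_meg < 0 || smooth_meg >= 1) {
    stop("smoothing coefficients must be in [0, 1)")
  }
  if (is.null(effect_pairs)) {
    effect_pairs <- default_effect_pairs(C_fmri, C_meg, bands)
  }
  effect_pairs <- validate_effect_pairs(effect_pairs, C_fmri, C_meg, bands)
  structure(list(
    n_sz = as.integer(n_sz), n_hc = as.integer(n_hc),
    C_fmri = as.integer(C_fmri), C_meg = as.integer(C_meg),
    T_fmri = as.integer(T_fmri), T_meg = as.integer(T_meg),
    bands = bands, effect_pairs = effect_pairs,
    n_states = as.integer(n_states), dwell = dwell,
    static_weight = static_weight,
    smooth_fmri = smooth_fmri, smooth_meg = smooth_meg,
    base_strength = base_strength, state_strength = state_strength,
    seed = as.integer(seed)
  ), class = "mmfnc_sim_config")
}

validate_effect_pairs <- function(ep, C_fmri, C_meg, bands) {
  ep <- as.data.frame(ep)
  need <- c("source", "i", "j", "dr")
  if (!all(need %in% names(ep))) {
    stop("effect_pairs needs columns source, i, j, dr")
  }
  ok_src <- c("fmri", bands)
  if (nrow(ep) > 0) {
    if (!all(ep$source %in% ok_src)) stop("effect_pairs: unknown source")
    Cs <- ifelse(ep$source == "fmri", C_fmri, C_meg)
    if (any(ep$i < 1 | ep$j <= ep$i | ep$j > Cs)) {
      stop("effect_pairs: need 1 <= i < j <= C for each source")
    }
    if (any(abs(ep$dr) >= 2)) stop("effect_pairs: |dr| must be < 2")
  }
  ep
}

#' Default planted-effect layout
#'
#' Plants block-structured group differences of |dr| = 0.3 in fMRI
#' (12 pairs), delta (9), alpha (4) and beta (22), and none in theta or
#' gamma, emulating the qualitative pattern of frontal/default-mode
#' hyper/hypo-connectivity blocks. Pair indices are arbitrary; no
#' anatomical claim is attached.
#'
#' @param C_fmri,C_meg component counts.
#' @param bands band names in play.
#' @param dr effect magnitude.
#' @return data.frame usable as `effect_pairs` in [simulation_config()].
#' @export
default_effect_pairs <- function(C_fmri = 38, C_meg = 32,
                                 bands = c("delta", "theta", "alpha", "beta", "gamma"),
                                 dr = 0.3) {
  block_pairs <- function(members) {
    pi <- pair_index(length(members))
    data.frame(i = members[pi$i], j = members[pi$j])
  }
  out <- list()
  # fMRI: 12 pairs = two 4-component blocks (6 hyper, 6 hypo)
  b1 <- block_pairs(1:4);  b1$dr <- dr
  b2 <- block_pairs(5:8);  b2$dr <- -dr
  out$fmri <- cbind(source = "fmri", rbind(b1, b2))
  if ("delta" %in% bands) {
    d1 <- block_pairs(1:4); d1$dr <- dr            # 6 pairs
    d2 <- data.frame(i = c(5, 5, 6), j = c(6, 7, 7), dr = -dr) # +3 = 9
    out$delta <- cbind(source = "delta", rbind(d1, d2))
  }
  if ("alpha" %in% bands) {
    a <- data.frame(i = c(1, 1, 2, 4), j = c(2, 3, 3, 5), dr = dr)
    out$alpha <- cbind(source = "alpha", a)
  }
  if ("beta" %in% bands) {
    bb <- block_pairs(1:7); bb$dr <- dr            # 21 pairs
    bb <- rbind(bb, data.frame(i = 8, j = 9, dr = -dr)) # 22
    out$beta <- cbind(source = "beta", bb)
  }
  ep <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # at reduced component counts, keep only the pairs that exist
  Cs <- ifelse(ep$source == "fmri", C_fmri, C_meg)
  ep[ep$j <= Cs, , drop = FALSE]
}

#' Build the per-group generative model
#'
#' For every source (fMRI and each band) a baseline correlation matrix is
#' drawn; the HC group uses it as its static structure, and the SZ group
#' is identical except that each planted effect pair is perturbed by its
#' `dr` and the matrix repaired to the nearest SPD correlation matrix
#' (eigenvalue clipping at 1e-6 then renormalization to unit diagonal).
#' Each group additionally receives `n_states` state correlation matrices:
#' shared random perturbations of the baseline, with the group's planted
#' differences applied, so the dynamics carry the same group signal.
#'
#' @param config an [simulation_config()] object.
#' @return An object of class `mmfnc_group_model`: per-source list with
#'   per-group static and state correlation matrices (plus Cholesky
#'   factors) and source metadata.
#' @export
build_group_model <- function(config) {
  stopifnot(inherits(config, "mmfnc_sim_config"))
  with_seed(derive_seed(config$seed, 1), {
    sources <- c("fmri", config$bands)
    model <- lapply(sources, function(src) {
      C <- if (src == "fmri") config$C_fmri else config$C_meg
      Tn <- if (src == "fmri") config$T_fmri else config$T_meg
      base <- random_correlation(C, config$base_strength)
      ep <- config$effect_pairs[config$effect_pairs$source == src, , drop = FALSE]
      static <- list(HC = base, SZ = plant_effects(base, ep))
      # state templates shared across groups (avoiding the planted pairs);
      # the planted group differences are re-applied per group so the
      # dynamics carry the same signal as the static structure
      deltas <- lapply(seq_len(config$n_states), function(s) {
        random_perturbation(C, config$state_strength, exclude = ep)
      })
      states <- lapply(c(HC = "HC", SZ = "SZ"), function(g) {
        lapply(deltas, function(d) {
          st <- spd_correlation(base + d)
          plant_effects(st, ep, repair_tol = 0.25, clip = TRUE)
        })
      })
      list(source = src, C = C, T = Tn,
           modality = if (src == "fmri") "fmri" else "meg",
           band = if (src == "fmri") "none" else src,
           smooth = if (src == "fmri") config$smooth_fmri else config$smooth_meg,
           static = static, states = states,
           chol_static = lapply(static, chol),
           chol_states = lapply(states, function(g) lapply(g, chol)))
    })
    names(model) <- sources
    structure(list(sources = model, config = config), class = "mmfnc_group_model")
  })
}

# Baseline correlation matrix: low-rank factor structure plus noise,
# scaled so typical off-diagonals have magnitude ~ strength.
random_correlation <- function(C, strength) {
  d <- max(2L, C %/% 4L)
  W <- matrix(stats::rnorm(C * d), C, d)
  S <- tcrossprod(W) / d
  R <- stats::cov2cor(S)
  spd_correlation(diag(1 - strength, C) + strength * R)
}

random_perturbation <- function(C, strength, exclude = NULL) {
  pi <- pair_index(C)
  avail <- seq_len(nrow(pi))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    banned <- paste(exclude$i, exclude$j)
    avail <- avail[!paste(pi$i, pi$j) %in% banned]
  }
  n_touch <- min(length(avail), max(1L, round(0.15 * C * (C - 1) / 2)))
  if (n_touch == 0L) return(matrix(0, C, C))
  pick <- avail[sample.int(length(avail), n_touch)]
  D <- matrix(0, C, C)
  vals <- strength * sample(c(-1, 1), n_touch, replace = TRUE) *
    stats::runif(n_touch, 0.5, 1)
  D[cbind(pi$i[pick], pi$j[pick])] <- vals
  D + t(D)
}

# Perturb planted pairs by dr, then repair to an SPD correlation matrix.
# Errors out if the perturbation cannot keep targets in (-1, 1) or if
# repair moves the planted values too far from their targets.
plant_effects <- function(R, ep, repair_tol = 0.1, clip = FALSE) {
  if (nrow(ep) == 0L) return(R)
  R2 <- R
  idx <- cbind(ep$i, ep$j)
  target <- R[idx] + ep$dr
  if (any(abs(target) >= 1)) {
    if (clip) {
      target <- sign(target) * pmin(abs(target), 0.97)
    } else {
      stop("planted effect drives a correlation outside (-1, 1); use a smaller dr")
    }
  }
  R2[idx] <- target
  R2[cbind(ep$j, ep$i)] <- target
  R2 <- spd_correlation(R2)
  if (max(abs(R2[idx] - target)) > repair_tol) {
    stop("SPD repair moved planted correlations by more than the repair tolerance; use a smaller dr")
  }
  R2
}

#' Simulate one subject
#'
#' Draws, for each source, a first-order Markov state sequence (stay
#' probability `dwell`), samples each time point from the active state's
#' correlation matrix, mixes in an i.i.d. stationary component with the
#' group's static correlation structure (weight `static_weight`), and
#' applies the modality's exponential low-pass filter. Because the same
#' filter acts on every component, zero-lag correlations are preserved.
#'
#' @param model an [build_group_model()] result.
#' @param group `"HC"` or `"SZ"`.
#' @param subject_id identifier.
#' @param seed subject seed.
#' @return list with `tcs` (named list of `mmfnc_tcs` per source) and
#'   `states` (named list of integer state sequences).
#' @export
simulate_subject <- function(model, group, subject_id, seed) {
  stopifnot(inherits(model, "mmfnc_group_model"))
  group <- match_group(group)
  cfg <- model$config
  with_seed(seed, {
    tcs <- list()
    states <- list()
    for (src in names(model$sources)) {
      m <- model$sources[[src]]
      Tn <- m$T; C <- m$C
      seq_s <- markov_sequence(Tn, cfg$n_states, cfg$dwell)
      Z <- matrix(stats::rnorm(Tn * C), Tn, C)
      for (s in unique(seq_s)) {
        rows <- which(seq_s == s)
        Z[rows, ] <- Z[rows, , drop = FALSE] %*% m$chol_states[[group]][[s]]
      }
      S <- matrix(stats::rnorm(Tn * C), Tn, C) %*% m$chol_static[[group]]
      X <- sqrt(1 - cfg$static_weight) * Z + sqrt(cfg$static_weight) * S
      if (m$smooth > 0) X <- exp_smooth(X, m$smooth)
      tcs[[src]] <- component_timecourses(
        X, subject_id = subject_id, group = group,
        modality = m$modality, band = m$band)
      states[[src]] <- seq_s
    }
    list(tcs = tcs, states = states)
  })
}

markov_sequence <- function(Tn, k, dwell) {
  s <- integer(Tn)
  s[1] <- sample.int(k, 1)
  if (k == 1L || dwell >= 1) {
    s[] <- s[1]
    return(s)
  }
  stay <- stats::runif(Tn - 1) < dwell
  for (t in 2:Tn) {
    if (stay[t - 1]) {
      s[t] <- s[t - 1]
    } else {
      others <- setdiff(seq_len(k), s[t - 1])
      s[t] <- others[sample.int(k - 1L, 1)]
    }
  }
  s
}

# First-order exponential low-pass, applied per column, then rescaled to
# unit stationary variance gain.
exp_smooth <- function(X, a) {
  Y <- X
  for (t in 2:nrow(X)) Y[t, ] <- a * Y[t - 1, ] + (1 - a) * X[t, ]
  Y / sqrt((1 - a)^2 / (1 - a^2))
}

#' Simulate a full study
#'
#' @param config an [simulation_config()] object.
#' @return list with `dataset` (an `mmfnc_study`) and `truth` (planted
#'   effect pairs, per-group correlation matrices, per-subject state
#'   sequences).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "mmfnc_sim_config"))
  model <- build_group_model(config)
  n <- config$n_sz + config$n_hc
  groups <- c(rep("SZ", config$n_sz), rep("HC", config$n_hc))
  ids <- sprintf("S%03d", seq_len(n))
  seeds <- with_seed(derive_seed(config$seed, 2), sample.int(2^30, n))
  subjects <- vector("list", n)
  state_truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_subject(model, groups[i], ids[i], seeds[i])
    subjects[[i]] <- list(subject_id = ids[i], group = groups[i], tcs = sim$tcs)
    state_truth[[i]] <- sim$states
  }
  names(state_truth) <- ids
  dataset <- study_dataset(subjects, metadata = list(seed = config$seed,
                                                     provenance = "mmfnc synthetic cohort"))
  truth <- list(effect_pairs = config$effect_pairs,
                static = lapply(model$sources, function(m) m$static),
                states = lapply(model$sources, function(m) m$states),
                state_sequences = state_truth)
  list(dataset = dataset, truth = truth)
}
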