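#' Default pipeline configuration
#'
#' Nested configuration mirroring the module parameters; with an empty
#' user config, `run_all()` reproduces the full study layout (91-subject
#' synthetic cohort, fMRI + five MEG bands, w = 31, sigma = 3, k = 5,
#' q = 0.05) at its defaults.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out = NULL,
    simulate = list(
      n_sz = 46L, n_hc = 45L, C_fmri = 38L, C_meg = 32L,
      T_fmri = 149L, T_meg = 300L,
      bands = c("delta", "theta", "alpha", "beta", "gamma"),
      n_states = 5L, dwell = 0.9, static_weight = 0.5,
      smooth_fmri = 0.6, smooth_meg = 0.3,
      base_strength = 0.25, state_strength = 0.6,
      effect_dr = 0.3,
      write_timecourses = FALSE
    ),
    static = list(q = 0.05, max_lag = 0L),
    dynamic = list(w = 31L, sigma = 3, step = 1L, k = 5L,
                   lambda = "cv", lambda_min = 0.01, lambda_max = 1,
                   lambda_n = 10L, cv_folds = 3L),
    classify = list(classifiers = c("ldc", "nbc", "nsvm"),
                    svm_cost = 1, svm_gamma = NULL),
    ensemble = list(enabled = TRUE)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; merges it over
#' [default_config()], rejects unknown keys (naming the offending key
#' path), and checks parameter ranges.
#'
#' @param config path to a YAML config file, a nested list, or `NULL`
#'   (pure defaults).
#' @return validated nested configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  merged <- merge_config(default_config(), config, path = "")
  cfg <- merged
  d <- cfg$dynamic
  if (d$w < 3) stop("config dynamic.w: window width must be >= 3")
  if (d$sigma < 0) stop("config dynamic.sigma must be >= 0")
  if (d$step < 1) stop("config dynamic.step must be >= 1")
  if (d$k < 1) stop("config dynamic.k must be >= 1")
  if (cfg$static$q <= 0 || cfg$static$q >= 1) stop("config static.q must be in (0, 1)")
  if (cfg$simulate$dwell <= 0 || cfg$simulate$dwell > 1) {
    stop("config simulate.dwell must be in (0, 1]")
  }
  if (!all(cfg$classify$classifiers %in% c("ldc", "nbc", "nsvm"))) {
    stop("config classify.classifiers: unknown classifier")
  }
  cfg
}

merge_config <- function(base, user, path = "") {
  if (!is.list(user)) return(user)
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(base)) stop(sprintf("unknown config key: %s", full))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Run the full pipeline end to end
#'
#' simulate -> static and dynamic FNC -> LOOCV classification per source
#' and per fMRI+band fusion -> majority-vote ensembles; writes results and
#' a manifest (parameters, seeds, artifact hashes) when an output
#' directory is configured.
#'
#' @param config a config list/path accepted by [validate_config()].
#' @param dataset optionally, an existing `mmfnc_study` to analyse
#'   instead of simulating one.
#' @param modes which FNC pipelines to run (default both).
#' @return list of class `mmfnc_run`: `static` and/or `dynamic`
#'   (`mmfnc_loocv` objects), `ensembles` (accuracy per panel and
#'   classifier), `config`, `manifest`.
#' @export
run_all <- function(config = NULL, dataset = NULL,
                    modes = c("static", "dynamic")) {
  cfg <- validate_config(config)
  modes <- match.arg(modes, several.ok = TRUE)
  t0 <- Sys.time()
  manifest <- list(started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   seed = cfg$seed, config = cfg, stages = list())

  run_stage <- function(name, expr) {
    stage_log(name, "start")
    t <- system.time(res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    }))
    manifest$stages[[name]] <<- list(elapsed_s = round(unname(t["elapsed"]), 2),
                                     seed = derive_seed(cfg$seed, length(manifest$stages)))
    stage_log(name, sprintf("done in %.1fs", t["elapsed"]))
    res
  }

  truth <- NULL
  if (is.null(dataset)) {
    sim <- run_stage("simulate", {
      s <- cfg$simulate
      s$bands <- unlist(s$bands) %||% character(0)
      sim_cfg <- simulation_config(
        n_sz = s$n_sz, n_hc = s$n_hc, C_fmri = s$C_fmri, C_meg = s$C_meg,
        T_fmri = s$T_fmri, T_meg = s$T_meg, bands = s$bands,
        effect_pairs = default_effect_pairs(s$C_fmri, s$C_meg, s$bands,
                                            dr = s$effect_dr),
        n_states = s$n_states, dwell = s$dwell,
        static_weight = s$static_weight,
        smooth_fmri = s$smooth_fmri, smooth_meg = s$smooth_meg,
        base_strength = s$base_strength, state_strength = s$state_strength,
        seed = cfg$seed)
      simulate_study(sim_cfg)
    })
    dataset <- sim$dataset
    truth <- sim$truth
  }

  bands <- setdiff(ordered_sources(dataset$sources), "fmri")
  fused <- if ("fmri" %in% dataset$sources) {
    lapply(bands, function(b) c("fmri", b))
  } else list()
  sources <- c(as.list(ordered_sources(dataset$sources)), fused)

  results <- list()
  if ("static" %in% modes) {
    results$static <- run_stage("static_fnc", {
      run_pipeline_loocv(dataset, mode = "static", sources = sources,
                         classifiers = cfg$classify$classifiers,
                         q = cfg$static$q, max_lag = cfg$static$max_lag,
                         seed = derive_seed(cfg$seed, 10))
    })
  }
  if ("dynamic" %in% modes) {
    results$dynamic <- run_stage("dynamic_fnc", {
      d <- cfg$dynamic
      grid <- exp(seq(log(d$lambda_min), log(d$lambda_max),
                      length.out = d$lambda_n))
      run_pipeline_loocv(dataset, mode = "dynamic", sources = sources,
                         classifiers = cfg$classify$classifiers,
                         k = d$k, spec = make_taper(d$w, d$sigma, d$step),
                         lambda = d$lambda, grid = grid,
                         n_folds = d$cv_folds,
                         seed = derive_seed(cfg$seed, 20))
    })
  }

  ensembles <- list()
  if (isTRUE(cfg$ensemble$enabled)) {
    ensembles <- run_stage("ensemble", {
      out <- list()
      for (mode in names(results)) {
        r <- results[[mode]]
        panel_defs <- list(
          meg = intersect(c("delta", "alpha", "beta", "theta", "gamma"),
                          r$source_names),
          fmri_meg = grep("^fmri\\+", r$source_names, value = TRUE))
        for (pd in names(panel_defs)) {
          members <- panel_defs[[pd]]
          if (length(members) < 2) next
          for (cl in r$classifiers) {
            ea <- ensemble_accuracy(r, cl, members)
            out[[paste(mode, pd, cl, sep = ".")]] <- ea$accuracy
          }
        }
      }
      out
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (length(results)) {
      rp <- file.path(cfg$out, "results.json")
      write_results(unname(results), rp)
      paths <- c(paths, rp)
    }
    ep <- file.path(cfg$out, "ensembles.json")
    jsonlite::write_json(ensembles, ep, auto_unbox = TRUE, digits = 10)
    paths <- c(paths, ep)
    manifest$artifacts <- lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  structure(c(results, list(ensembles = ensembles, truth = truth,
                            config = cfg, manifest = manifest)),
            class = "mmfnc_run")
}

#' @export
print.mmfnc_run <- function(x, ...) {
  cat("mmfnc pipeline run\n")
  for (mode in intersect(c("static", "dynamic"), names(x))) {
    cat(sprintf("\n-- %s FNC --\n", mode))
    print(summary(x[[mode]]))
  }
  if (length(x$ensembles)) {
    cat("\n-- ensembles --\n")
    for (nm in names(x$ensembles)) {
      cat(sprintf("  %s: %.2f%%\n", nm, 100 * x$ensembles[[nm]]))
    }
  }
  invisible(x)
}
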