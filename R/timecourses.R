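#' Component timecourse set
#'
#' The elementary data object: one subject's T x C matrix of component
#' timecourses for one modality/band, with sampling metadata. fMRI
#' timecourses have no band (`band = "none"`); MEG envelope timecourses
#' carry one of the five canonical bands (delta, theta, alpha, beta, gamma).
#'
#' @param data numeric T x C matrix (rows = samples, columns = components).
#' @param subject_id opaque subject identifier.
#' @param group group label, `"HC"` or `"SZ"`.
#' @param modality `"fmri"` or `"meg"`.
#' @param band `"none"` for fMRI; one of `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"gamma"` for MEG.
#' @param sampling_rate sampling rate in Hz. Defaults: 0.5 for fMRI
#'   (TR = 2 s), 1.0 for MEG envelopes.
#' @return An object of class `mmfnc_tcs`.
#' @export
component_timecourses <- function(data, subject_id, group,
                                  modality = c("fmri", "meg"),
                                  band = "none", sampling_rate = NULL) {
  modality <- match.arg(modality)
  group <- match_group(group)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("timecourse data must be numeric")
  if (nrow(data) < 2L) stop("T < 2: need at least 2 samples")
  if (ncol(data) < 2L) stop("C < 2: need at least 2 components")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite value at row %d, column %s",
                 bad[1, 1], colnames(data)[bad[1, 2]] %||% as.character(bad[1, 2])))
  }
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  if (modality == "fmri") {
    if (!identical(band, "none")) stop("fMRI timecourses must have band = \"none\"")
  } else {
    if (!band %in% bands) {
      stop(sprintf("MEG band must be one of %s", paste(bands, collapse = ", ")))
    }
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- if (modality == "fmri") 0.5 else 1.0
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (is.null(colnames(data))) colnames(data) <- sprintf("IC%02d", seq_len(ncol(data)))
  structure(list(
    subject_id = as.character(subject_id),
    group = group,
    modality = modality,
    band = band,
    data = data,
    sampling_rate = sampling_rate
  ), class = "mmfnc_tcs")
}

group_levels <- function() c("HC", "SZ")

match_group <- function(group) {
  group <- as.character(group)
  if (length(group) != 1L || !group %in% group_levels()) {
    stop("group must be \"HC\" or \"SZ\"")
  }
  group
}

#' @export
print.mmfnc_tcs <- function(x, ...) {
  cat(sprintf("Component timecourses: subject %s (%s), %s%s\n",
              x$subject_id, x$group, x$modality,
              if (x$band != "none") paste0("/", x$band) else ""))
  cat(sprintf("  T = %d samples x C = %d components @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' Read a TSV timecourse table
#'
#' Reads a tab-separated numeric table (header row of component identifiers,
#' rows = samples) into a validated [component_timecourses()] object.
#'
#' @param path path to the TSV file.
#' @inheritParams component_timecourses
#' @return An `mmfnc_tcs` object.
#' @export
read_timecourses <- function(path, subject_id, group, modality = c("fmri", "meg"),
                             band = "none", sampling_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) < 1L || ncol(tab) < 1L) stop("empty timecourse table")
  for (cn in names(tab)) {
    if (!is.numeric(tab[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(tab[[cn]])))))[1]
      stop(sprintf("non-numeric cell at row %s, column %s",
                   if (is.na(bad)) "?" else bad, cn))
    }
  }
  component_timecourses(as.matrix(tab), subject_id = subject_id, group = group,
                        modality = modality, band = band,
                        sampling_rate = sampling_rate)
}

#' Write a timecourse set to TSV
#' @param x an `mmfnc_tcs` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(x, path) {
  stopifnot(inherits(x, "mmfnc_tcs"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a study dataset
#'
#' A study dataset collects, for every subject, one timecourse set per
#' data source (fMRI plus MEG bands), with one group label per subject and
#' identical source coverage across subjects.
#'
#' @param subjects a list; each element is a list with fields `subject_id`,
#'   `group`, and `tcs` (a named list of `mmfnc_tcs`, keyed by source name,
#'   e.g. `"fmri"`, `"delta"`).
#' @param metadata optional list of provenance notes (seed etc.).
#' @return An object of class `mmfnc_study`.
#' @export
study_dataset <- function(subjects, metadata = list()) {
  if (length(subjects) < 1L) stop("no subjects")
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  groups <- vapply(subjects, function(s) match_group(s$group), "")
  src <- sort(names(subjects[[1]]$tcs))
  for (s in subjects) {
    if (!identical(sort(names(s$tcs)), src)) {
      stop(sprintf("subject %s: source coverage differs from first subject",
                   s$subject_id))
    }
    for (nm in names(s$tcs)) {
      if (!inherits(s$tcs[[nm]], "mmfnc_tcs")) {
        stop("each tcs entry must be an mmfnc_tcs object")
      }
    }
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, groups = stats::setNames(groups, ids),
                 sources = src, metadata = metadata),
            class = "mmfnc_study")
}

#' @export
print.mmfnc_study <- function(x, ...) {
  tab <- table(factor(x$groups, levels = group_levels()))
  cat(sprintf("FNC study dataset: %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  cat(sprintf("  sources: %s\n", paste(x$sources, collapse = ", ")))
  invisible(x)
}

# Ordered source names: fmri first, then canonical band order.
ordered_sources <- function(sources) {
  canon <- c("fmri", "delta", "theta", "alpha", "beta", "gamma")
  c(intersect(canon, sources), setdiff(sources, canon))
}

#' Write classification results to JSON
#'
#' Serializes a LOOCV result (see [run_pipeline_loocv()]) to a stable JSON
#' document: per-subject true/predicted labels per classifier and source,
#' per-fold selected features, and summary accuracies. Output is
#' byte-stable for identical inputs.
#'
#' @param results an `mmfnc_loocv` object or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "mmfnc_loocv")) results <- list(results)
  if (length(results) == 0L) stop("nothing to write: empty result set")
  doc <- lapply(results, loocv_to_list)
  names(doc) <- vapply(seq_along(results), function(i) {
    results[[i]]$label %||% sprintf("result_%02d", i)
  }, "")
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write results to %s: %s", path, conditionMessage(e)))
  })
  invisible(path)
}

loocv_to_list <- function(r) {
  stopifnot(inherits(r, "mmfnc_loocv"))
  list(
    mode = r$mode,
    sources = r$source_names,
    classifiers = r$classifiers,
    predictions = lapply(seq_len(nrow(r$predictions)), function(i) {
      as.list(r$predictions[i, , drop = FALSE])
    }),
    selected_features = r$selected_features,
    accuracy = lapply(seq_len(nrow(r$accuracy)), function(i) {
      as.list(r$accuracy[i, , drop = FALSE])
    })
  )
}

#' Read results written by [write_results()]
#' @param path JSON path.
#' @return Nested list mirroring the written structure.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
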