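#' Concatenate feature matrices across sources
#'
#' Column-wise concatenation in the declared source order, with column
#' provenance retained in the column names (`source.feature`). All
#' sources must cover the same subjects in the same order.
#'
#' @param mats named list of subjects x features matrices.
#' @param order optional source order (default: list order).
#' @return fused feature matrix.
#' @export
concat_features <- function(mats, order = names(mats)) {
  stopifnot(length(mats) >= 1, !is.null(names(mats)))
  mats <- mats[order]
  rn <- rownames(mats[[1]])
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), rn)) {
      mism <- union(setdiff(rownames(mats[[nm]]), rn), setdiff(rn, rownames(mats[[nm]])))
      stop(sprintf("subject mismatch in source %s: %s", nm,
                   paste(mism, collapse = ", ")))
    }
  }
  out <- do.call(cbind, lapply(names(mats), function(nm) {
    m <- as.matrix(mats[[nm]])
    cn <- colnames(m) %||% as.character(seq_len(ncol(m)))
    colnames(m) <- paste(nm, cn, sep = ".")
    m
  }))
  rownames(out) <- rn
  out
}

#' Build a vote panel
#'
#' @param members named list of prediction data.frames, each with columns
#'   `subject`, `predicted` and optionally `confidence`.
#' @return Object of class `mmfnc_panel`.
#' @export
vote_panel <- function(members) {
  if (length(members) < 2) stop("a vote panel needs at least 2 members")
  if (is.null(names(members)) || any(names(members) == "")) {
    stop("panel members must be named")
  }
  subj <- sort(unique(members[[1]]$subject))
  for (nm in names(members)) {
    missing <- setdiff(subj, members[[nm]]$subject)
    extra <- setdiff(members[[nm]]$subject, subj)
    if (length(missing) || length(extra)) {
      stop(sprintf("member %s does not cover the same subjects (missing: %s)",
                   nm, paste(missing, collapse = ", ")))
    }
  }
  structure(list(members = members, subjects = subj), class = "mmfnc_panel")
}

#' Equal-weight majority vote
#'
#' Each member contributes one equally weighted vote per subject; the
#' modal label wins. Ties are broken by the larger mean member confidence
#' for each label, and failing that by fixed class order (HC first); tied
#' subjects are flagged.
#'
#' @param panel an [vote_panel()] (or plain named list of member
#'   prediction frames).
#' @return data.frame with `subject`, `label`, `tie`.
#' @export
majority_vote <- function(panel) {
  if (!inherits(panel, "mmfnc_panel")) panel <- vote_panel(panel)
  lv <- group_levels()
  out <- lapply(panel$subjects, function(s) {
    votes <- vapply(panel$members, function(m) {
      m$predicted[match(s, m$subject)]
    }, "")
    conf <- vapply(panel$members, function(m) {
      cf <- m$confidence
      if (is.null(cf)) NA_real_ else cf[match(s, m$subject)]
    }, 0)
    counts <- table(factor(votes, levels = lv))
    tie <- counts[1] == counts[2]
    if (!tie) {
      label <- names(counts)[which.max(counts)]
    } else {
      mean_conf <- vapply(lv, function(g) {
        v <- abs(conf[votes == g])
        if (all(is.na(v)) || length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
      label <- if (!anyNA(mean_conf) && mean_conf[1] != mean_conf[2]) {
        lv[which.max(mean_conf)]
      } else lv[1]
    }
    data.frame(subject = s, label = label, tie = unname(tie),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the four canonical ensemble panels
#'
#' From per-member LOOCV prediction tables (one classifier), builds the
#' four ensembles of the framework: the static MEG panel (delta, alpha,
#' beta), the static fMRI+MEG panel (fmri+delta, fmri+alpha, fmri+beta),
#' the dynamic MEG panel (all five bands) and the dynamic fMRI+MEG panel
#' (fmri+each of the five bands).
#'
#' @param members named list of prediction data.frames keyed by member
#'   name (`"delta"`, `"fmri+delta"`, ...).
#' @param which subset of panel names to build (default all four).
#' @return named list of `mmfnc_panel` objects.
#' @export
build_canonical_panels <- function(members,
                                   which = c("static_meg", "static_fmri_meg",
                                             "dynamic_meg", "dynamic_fmri_meg")) {
  if (length(members) == 0) stop("empty results: no panel members")
  defs <- list(
    static_meg = c("delta", "alpha", "beta"),
    static_fmri_meg = c("fmri+delta", "fmri+alpha", "fmri+beta"),
    dynamic_meg = c("delta", "theta", "alpha", "beta", "gamma"),
    dynamic_fmri_meg = c("fmri+delta", "fmri+theta", "fmri+alpha",
                         "fmri+beta", "fmri+gamma"))
  out <- lapply(which, function(p) {
    need <- defs[[p]]
    miss <- setdiff(need, names(members))
    if (length(miss)) {
      stop(sprintf("panel %s: missing member(s) %s", p,
                   paste(miss, collapse = ", ")))
    }
    vote_panel(members[need])
  })
  names(out) <- which
  out
}

#' Ensemble accuracy from a LOOCV result
#'
#' Builds a vote panel from the per-source predictions of one classifier
#' inside an `mmfnc_loocv` result and returns the majority-vote accuracy.
#'
#' @param result an `mmfnc_loocv`.
#' @param classifier classifier kind to ensemble over.
#' @param sources panel member source names (default: all in the result).
#' @return list with `accuracy`, `votes` (majority_vote output merged
#'   with truth).
#' @export
ensemble_accuracy <- function(result, classifier, sources = NULL) {
  pr <- result$predictions[result$predictions$classifier == classifier, ]
  if (is.null(sources)) sources <- unique(pr$source)
  members <- lapply(sources, function(s) {
    d <- pr[pr$source == s, c("subject", "predicted", "confidence")]
    d
  })
  names(members) <- sources
  votes <- majority_vote(vote_panel(members))
  truth <- result$predictions[!duplicated(result$predictions$subject),
                              c("subject", "truth")]
  votes <- merge(votes, truth, by = "subject")
  list(accuracy = mean(votes$label == votes$truth), votes = votes)
}
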