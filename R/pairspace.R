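#' Upper-triangle pair index for C components
#'
#' Enumerates all unordered component pairs (i, j) with i < j in row-major
#' upper-triangle order: (1,2), (1,3), ..., (1,C), (2,3), .... This single
#' ordering is the pair-space convention used everywhere in the package, so
#' static and dynamic connectivity features are always aligned.
#'
#' @param C number of components (>= 2).
#' @return A data.frame with integer columns `i` and `j`, one row per pair;
#'   `C*(C-1)/2` rows in total.
#' @examples
#' pair_index(4)
#' nrow(pair_index(32)) # 496
#' @export
pair_index <- function(C) {
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 2 || C != round(C)) {
    stop("`C` must be a single integer >= 2")
  }
  C <- as.integer(C)
  i <- rep.int(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param m symmetric numeric C x C matrix.
#' @param tol symmetry tolerance (maximum allowed |m - t(m)|).
#' @return Numeric vector of length `C*(C-1)/2` ordered by [pair_index()].
#' @seealso [unvectorize_upper()]
#' @export
vectorize_upper <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be a square matrix")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("`m` is not symmetric: max asymmetry %.3g exceeds tol %.3g",
                 asym, tol))
  }
  pi <- pair_index(nrow(m))
  m[cbind(pi$i, pi$j)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' @param v numeric vector of length `C*(C-1)/2` in [pair_index()] order.
#' @param diag value(s) for the diagonal (recycled to length C).
#' @return Symmetric C x C matrix.
#' @export
unvectorize_upper <- function(v, diag = 1) {
  P <- length(v)
  C <- (1 + sqrt(1 + 8 * P)) / 2
  if (P < 1 || abs(C - round(C)) > 1e-9) {
    stop("length of `v` is not C*(C-1)/2 for any integer C")
  }
  C <- as.integer(round(C))
  m <- matrix(0, C, C)
  pi <- pair_index(C)
  m[cbind(pi$i, pi$j)] <- v
  m <- m + t(m)
  base::diag(m) <- rep_len(diag, C)
  m
}

#' Human-readable pair labels ("IC01-IC02", ...)
#' @param C number of components.
#' @param names optional component names (default "IC01", ...).
#' @return character vector of pair labels in pair-index order.
#' @export
pair_labels <- function(C, names = NULL) {
  if (is.null(names)) names <- sprintf("IC%02d", seq_len(C))
  pi <- pair_index(C)
  paste(names[pi$i], names[pi$j], sep = "-")
}
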