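# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go
# through this so results are reproducible from explicit seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stage offset; kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647)
}

# Clip eigenvalues of a symmetric matrix at `floor` and renormalize to a
# correlation matrix (unit diagonal). Used to repair near-SPD matrices after
# planting effects or adding perturbations.
spd_correlation <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  m2 <- e$vectors %*% (t(e$vectors) * vals)
  m2 <- (m2 + t(m2)) / 2
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  m2
}

# Largest principal angle (radians) between the column spaces of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg))
}
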