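# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded generators compose cleanly.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Pair indexing for the lower-triangle moment vector: pairs (a < b) ordered
# as in combn(J, 2), which matches Sigma[lower.tri(Sigma)].
pair_index <- function(J) {
  idx <- combn(J, 2)
  list(a = idx[1L, ], b = idx[2L, ], n = ncol(idx))
}

#' Randomized Halton sequence mapped to standard normal deviates
#'
#' Low-discrepancy points (bases 2, 3, 5, 7, 11, ...) with a seeded
#' Cranley-Patterson rotation, transformed through the normal quantile
#' function. Used as integration nodes for the marginal ordinal likelihood.
#'
#' @param n number of points.
#' @param dim dimension (number of latent factors), at most 10.
#' @param seed integer seed for the random shift; `NULL` for an unshifted
#'   sequence.
#' @return an `n` x `dim` matrix of N(0,1)-marginal quasi-random deviates.
#' @export
halton_normal <- function(n, dim, seed = NULL) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(bases)) stopf("halton_normal supports at most %d dimensions",
                                 length(bases))
  shift <- if (is.null(seed)) rep(0, dim) else with_seed(seed, runif(dim))
  u <- matrix(0, n, dim)
  idx <- seq_len(n)
  for (d in seq_len(dim)) {
    b <- bases[d]
    h <- numeric(n)
    f <- 1 / b
    k <- idx
    while (any(k > 0)) {
      h <- h + (k %% b) * f
      k <- k %/% b
      f <- f / b
    }
    u[, d] <- (h + shift[d]) %% 1
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u)
}

# format "0.029 (0.028, 0.030)"
format_ci3 <- function(x, lo, hi) {
  sprintf("%.3f (%.3f, %.3f)", x, lo, hi)
}
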