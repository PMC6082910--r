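# Model-based omega reliability coefficients from a fitted bifactor
# solution, computed on the latent-response (polychoric) scale from the
# standardized loadings.

#' Omega reliability coefficients for a bifactor fit
#'
#' From standardized bifactor loadings (general loadings `lambda_g`,
#' block-specific loadings `lambda_s`, residual variances
#' `1 - lambda_g^2 - lambda_s^2`):
#' total-score reliability
#' `omega = ((sum lambda_g)^2 + sum_s (sum_{i in s} lambda_s)^2) /
#'          ((sum lambda_g)^2 + sum_s (sum lambda_s)^2 + sum resid)`,
#' hierarchical omega `omega_h` replaces the numerator by
#' `(sum lambda_g)^2` alone, and the per-block subscale coefficients
#' `omega_s` / `omega_hs` apply the same algebra to each block's items,
#' with `omega_hs` crediting only the block's specific factor (the share of
#' subscale variance beyond the general factor).
#'
#' @param fitted a bifactor [fit_dwls()] (or structural) result, or a list
#'   with elements `loadings` (item x factor, general factor first),
#'   `structure = "bifactor"` and per-item block assignment in
#'   `spec$blocks`.
#' @return object of class `omega_set`: `omega`, `omega_h`, and per-block
#'   `omega_s`, `omega_hs`.
#' @export
compute_omegas <- function(fitted) {
  if (!identical(fitted$structure, "bifactor"))
    stopf("omega coefficients require a bifactor fit, got '%s'",
          fitted$structure)
  L <- fitted$loadings
  blocks <- fitted$spec$blocks
  block_names <- fitted$spec$block_names
  lg <- L[, 1L]
  ls <- rowSums(L[, -1L, drop = FALSE])  # one specific loading per item
  resid <- 1 - lg^2 - ls^2
  if (any(resid < 0))
    stopf("Heywood item(s) with negative residual variance: %s",
          paste(rownames(L)[resid < 0], collapse = ", "))
  sum_s2 <- sapply(block_names, function(b) sum(ls[blocks == b])^2)
  num_general <- sum(lg)^2
  total <- num_general + sum(sum_s2) + sum(resid)
  omega <- (num_general + sum(sum_s2)) / total
  omega_h <- num_general / total
  omega_s <- omega_hs <- setNames(numeric(length(block_names)), block_names)
  for (b in block_names) {
    sel <- blocks == b
    gen_b <- sum(lg[sel])^2
    spec_b <- sum(ls[sel])^2
    tot_b <- gen_b + spec_b + sum(resid[sel])
    omega_s[b] <- (gen_b + spec_b) / tot_b
    omega_hs[b] <- spec_b / tot_b
  }
  structure(list(omega = omega, omega_h = omega_h,
                 omega_s = omega_s, omega_hs = omega_hs),
            class = "omega_set")
}

#' @export
print.omega_set <- function(x, ...) {
  cat(sprintf("omega = %.3f, omega_H = %.3f\n", x$omega, x$omega_h))
  for (b in names(x$omega_s))
    cat(sprintf("  %s: omega_S = %.3f, omega_HS = %.3f\n", b,
                x$omega_s[b], x$omega_hs[b]))
  invisible(x)
}
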