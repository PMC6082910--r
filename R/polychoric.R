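# Polychoric and polyserial correlations, two-stage (limited-information)
# maximum likelihood: univariate thresholds first, then the latent
# bivariate-normal correlation with thresholds held fixed.

#' Estimate normal-ogive thresholds for an ordinal item
#'
#' Threshold `tau_k` is the standard-normal quantile of the cumulative
#' (optionally weighted) proportion through category `k`.
#'
#' @param x integer vector of categories `0..K-1` (NA allowed).
#' @param weights optional positive case weights.
#' @param n_categories number of categories `K`; defaults to
#'   `max(x, na.rm = TRUE) + 1`.
#' @return ascending numeric vector of `K - 1` thresholds.
#' @export
estimate_thresholds <- function(x, weights = NULL, n_categories = NULL) {
  obs <- !is.na(x)
  if (is.null(weights)) weights <- rep(1, length(x))
  x <- x[obs]; w <- weights[obs]
  if (length(x) == 0L) stopf("no observed responses")
  if (is.null(n_categories)) n_categories <- max(x) + 1L
  if (length(unique(x)) < 2L)
    stopf("item unidentifiable: single observed category")
  counts <- vapply(0:(n_categories - 1L),
                   function(k) sum(w[x == k]), numeric(1))
  cum <- cumsum(counts) / sum(counts)
  qnorm(pmin(pmax(cum[-n_categories], 1e-10), 1 - 1e-10))
}

#' Polychoric correlation between two ordinal items
#'
#' Two-stage estimate: thresholds fixed at their univariate values, then
#' the correlation of the latent bivariate normal maximizes the
#' contingency-table likelihood (Brent search on `(-bound, bound)`).
#' Pairwise-present observations are used; the asymptotic sampling variance
#' comes from the Fisher information of the correlation.
#'
#' @param x,y integer category vectors `0..K-1` (NA allowed).
#' @param weights optional positive case weights.
#' @param bound search bound on the correlation (default 0.995).
#' @param tol Brent tolerance.
#' @return list: `rho`, `se`, `avar`, `loglik`, `n` (pairwise weight),
#'   `thresholds` (list of the two vectors).
#' @export
estimate_polychoric <- function(x, y, weights = NULL, bound = 0.995,
                                tol = 1e-7) {
  if (is.null(weights)) weights <- rep(1, length(x))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L) stopf("fewer than 10 pairwise-complete observations")
  tau1 <- estimate_thresholds(x, weights)
  tau2 <- estimate_thresholds(y, weights)
  K1 <- length(tau1) + 1L; K2 <- length(tau2) + 1L
  tab <- matrix(0, K1, K2)
  xi <- x[ok] + 1L; yi <- y[ok] + 1L; wi <- weights[ok]
  for (r in seq_along(xi)) tab[xi[r], yi[r]] <- tab[xi[r], yi[r]] + wi[r]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    warnf("empty contingency margin; estimate may be unstable")
  fit <- .pc_fit_pair(tab, tau1, tau2, bound, tol)
  list(rho = fit$rho, se = sqrt(fit$avar), avar = fit$avar,
       loglik = fit$loglik, n = fit$n,
       thresholds = list(tau1, tau2))
}

#' Polychoric correlation matrix of an ordinal item table
#'
#' All pairwise two-stage polychoric estimates with pairwise-present data,
#' per-pair asymptotic variances, and (optionally) the per-observation
#' influence matrix used to assemble the asymptotic covariance of the whole
#' correlation vector for mean-and-variance adjusted test statistics and
#' sandwich standard errors.
#'
#' @param items integer matrix (respondent x item) of categories `0..K-1`,
#'   NA allowed; needs >= 2 observed categories per item.
#' @param weights optional positive case weights (length `nrow(items)`).
#' @param influence keep the `n` x `npairs` influence matrix.
#' @param bound,tol see [estimate_polychoric()].
#' @return object of class `polychoric_summary`: `R` (item x item
#'   correlation matrix), `avar` and `n_pairwise` (lower-triangle vectors in
#'   `combn(J, 2)` order), `thresholds` (per-item list), `influence`,
#'   `n`, `wtot`, `weights`.
#' @export
polychoric_matrix <- function(items, weights = NULL, influence = TRUE,
                              bound = 0.995, tol = 1e-7) {
  items <- as.matrix(items)
  J <- ncol(items)
  if (J < 2L) stopf("need at least two items")
  n <- nrow(items)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be non-negative, finite, length nrow(items)")
  taus <- lapply(seq_len(J), function(j)
    estimate_thresholds(items[, j], weights))
  y <- items
  storage.mode(y) <- "integer"
  y[is.na(y)] <- -1L
  res <- .pc_matrix_cpp(y, taus, as.numeric(weights), influence, bound, tol)
  R <- diag(J)
  R[lower.tri(R)] <- res$rho
  R <- R + t(R) - diag(J)
  dimnames(R) <- list(colnames(items), colnames(items))
  structure(list(
    R = R, avar = res$avar, n_pairwise = res$n,
    thresholds = setNames(taus, colnames(items)),
    influence = if (influence) res$influence else NULL,
    n = n, wtot = sum(weights), weights = weights,
    item_names = colnames(items)
  ), class = "polychoric_summary")
}

#' @export
print.polychoric_summary <- function(x, ...) {
  cat(sprintf("Polychoric summary: %d items, n = %d, correlations in [%.3f, %.3f]\n",
              length(x$thresholds), x$n, min(x$R[lower.tri(x$R)]),
              max(x$R[lower.tri(x$R)])))
  invisible(x)
}

# Polyserial correlation between a continuous variable and an ordinal item,
# two-stage: x treated as standard normal (standardized internally),
# thresholds from the item margins, rho by ML over the conditional ordinal
# likelihood. Returns rho, avar, and the per-observation influence values.
estimate_polyserial <- function(x, y, weights = NULL, bound = 0.99) {
  if (is.null(weights)) weights <- rep(1, length(x))
  ok <- !is.na(x) & !is.na(y)
  tau <- estimate_thresholds(y, weights)
  n_all <- length(x)
  xi <- x[ok]; yi <- y[ok]; wi <- weights[ok]
  wm <- sum(wi * xi) / sum(wi)
  ws <- sqrt(sum(wi * (xi - wm)^2) / sum(wi))
  xi <- (xi - wm) / ws
  K <- length(tau) + 1L
  up <- c(tau, Inf)[yi + 1L]
  lo <- c(-Inf, tau)[yi + 1L]
  ll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- pnorm((up - rho * xi) / s) - pnorm((lo - rho * xi) / s)
    sum(wi * log(pmax(p, 1e-300)))
  }
  opt <- optimize(ll, c(-bound, bound), maximum = TRUE, tol = 1e-8)
  rho <- opt$maximum
  # per-observation rho score by central difference
  score_at <- function(r, tau_use, xv = xi) {
    upk <- c(tau_use, Inf)[yi + 1L]
    lok <- c(-Inf, tau_use)[yi + 1L]
    h <- 1e-5
    s1 <- sqrt(1 - (r + h)^2); s0 <- sqrt(1 - (r - h)^2)
    p1 <- pnorm((upk - (r + h) * xv) / s1) - pnorm((lok - (r + h) * xv) / s1)
    p0 <- pnorm((upk - (r - h) * xv) / s0) - pnorm((lok - (r - h) * xv) / s0)
    (log(pmax(p1, 1e-300)) - log(pmax(p0, 1e-300))) / (2 * h)
  }
  u <- score_at(rho, tau)
  n_s <- sum(wi)
  info_unit <- sum(wi * u^2) / n_s
  # two-stage corrections: sampling error of the stage-1 nuisance
  # estimates (item thresholds; mean and sd used to standardize x)
  # propagates into rho through the cross-derivatives of the score
  counts <- vapply(0:(K - 1L), function(k) sum(wi[yi == k]), numeric(1))
  Fk <- cumsum(counts)[-K] / n_s
  u_corr <- u
  ht <- 1e-4
  for (k in seq_along(tau)) {
    tp <- tau; tp[k] <- tp[k] + ht
    tm <- tau; tm[k] <- tm[k] - ht
    Dk <- sum(wi * (score_at(rho, tp) - score_at(rho, tm))) / (2 * ht * n_s)
    psi_tau <- (as.numeric(yi <= (k - 1L)) - Fk[k]) / dnorm(tau[k])
    u_corr <- u_corr + Dk * psi_tau
  }
  # location/scale of x: shifting z by -d (influence z_i) and scaling by
  # (1 - e) (influence (z_i^2 - 1)/2)
  D_shift <- sum(wi * (score_at(rho, tau, xi - ht) -
                         score_at(rho, tau, xi + ht))) / (2 * ht * n_s)
  D_scale <- sum(wi * (score_at(rho, tau, xi * (1 - ht)) -
                         score_at(rho, tau, xi * (1 + ht)))) / (2 * ht * n_s)
  u_corr <- u_corr + D_shift * xi + D_scale * (xi^2 - 1) / 2
  u_corr <- u_corr / info_unit
  wtot <- sum(weights)
  psi <- numeric(n_all)
  psi[ok] <- (wtot / n_s) * wi * u_corr
  list(rho = rho, avar = sum((psi / wtot)^2), influence = psi, n = n_s)
}
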