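# Limited-information estimation of the four competing measurement
# structures: diagonally weighted least squares on the polychoric
# correlation vector with thresholds fixed at their univariate estimates
# (the WLSMV convention), mean-and-variance (Satterthwaite) adjusted test
# statistics, and absolute fit indices.

MODEL_STRUCTURES <- c("uncorrelated", "unidimensional", "correlated",
                      "bifactor")

#' Build a measurement-model specification
#'
#' Four structures over blocked ordinal items: (i) uncorrelated block
#' factors, (ii) a single unidimensional factor, (iii) correlated block
#' factors, (iv) a bifactor model with one general factor loading on every
#' item plus orthogonal block-specific factors. Factor variances are fixed
#' to 1 for identification; factor correlations are free only in the
#' correlated structure.
#'
#' @param structure one of `"uncorrelated"`, `"unidimensional"`,
#'   `"correlated"`, `"bifactor"`.
#' @param blocks character vector assigning each item to a block, or a
#'   named list `block -> item names` (order defines the item order).
#' @return object of class `model_spec`.
#' @export
build_model <- function(structure, blocks) {
  if (length(structure) != 1L || !structure %in% MODEL_STRUCTURES)
    stopf("unknown structure '%s'; must be one of %s",
          paste(structure, collapse = ","),
          paste(MODEL_STRUCTURES, collapse = ", "))
  if (is.list(blocks)) {
    item_names <- unlist(blocks, use.names = FALSE)
    blocks <- rep(names(blocks), lengths(blocks))
    names(blocks) <- item_names
  }
  block_names <- unique(blocks)
  block_idx <- match(blocks, block_names)
  J <- length(blocks)
  nb <- length(block_names)
  factor_names <- switch(structure,
    unidimensional = "GENERAL",
    bifactor = c("GENERAL", block_names),
    block_names)
  F <- length(factor_names)
  # free loading map: (item, factor) rows
  load_idx <- switch(structure,
    unidimensional = cbind(seq_len(J), 1L),
    uncorrelated = cbind(seq_len(J), block_idx),
    correlated = cbind(seq_len(J), block_idx),
    bifactor = rbind(cbind(seq_len(J), 1L),
                     cbind(seq_len(J), block_idx + 1L)))
  phi_free <- if (structure == "correlated" && nb > 1L)
    t(combn(nb, 2)) else matrix(integer(0), 0L, 2L)
  structure(list(
    structure = structure, blocks = blocks, block_names = block_names,
    block_idx = block_idx, item_names = names(blocks),
    factor_names = factor_names, n_items = J, n_factors = F,
    load_idx = load_idx, phi_free = phi_free,
    n_free_loadings = nrow(load_idx), n_free_phi = nrow(phi_free)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Measurement model '%s': %d items, %d factor(s), %d free loadings, %d free factor correlations\n",
              x$structure, x$n_items, x$n_factors, x$n_free_loadings,
              x$n_free_phi))
  invisible(x)
}

# ---- shared weighted-least-squares engine ---------------------------------

# Parameter layout: theta = c(loadings, phi off-diagonals, gamma).
# `n_exo = 1` appends a standardized exogenous regressor of all factors
# (MIMIC structural part); the moment vector is then
# c(item-item correlations, item-exposure correlations).
wls_layout <- function(spec, n_exo = 0L) {
  J <- spec$n_items; F <- spec$n_factors
  pr <- pair_index(J)
  rows_of_item <- lapply(seq_len(J), function(i) {
    sel <- which(pr$a == i | pr$b == i)
    list(rows = sel, partner = ifelse(pr$a[sel] == i, pr$b[sel], pr$a[sel]))
  })
  n_gamma <- if (n_exo > 0L) F else 0L
  list(spec = spec, J = J, F = F, pairA = pr$a, pairB = pr$b, d1 = pr$n,
       rows_of_item = rows_of_item, n_exo = n_exo, n_gamma = n_gamma,
       n_theta = spec$n_free_loadings + spec$n_free_phi + n_gamma)
}

wls_unpack <- function(theta, lay) {
  spec <- lay$spec
  nl <- spec$n_free_loadings; np <- spec$n_free_phi
  L <- matrix(0, lay$J, lay$F,
              dimnames = list(spec$item_names, spec$factor_names))
  L[spec$load_idx] <- theta[seq_len(nl)]
  gamma <- if (lay$n_gamma > 0L)
    theta[nl + np + seq_len(lay$n_gamma)] else rep(0, lay$F)
  Phi <- diag(lay$F)
  if (np > 0L) {
    ph <- theta[nl + seq_len(np)]
    for (k in seq_len(np)) {
      f <- spec$phi_free[k, 1L]; g <- spec$phi_free[k, 2L]
      Phi[f, g] <- Phi[g, f] <- ph[k]
    }
  }
  if (lay$n_gamma > 0L) {
    Phi <- Phi + tcrossprod(gamma)
    diag(Phi) <- 1  # residual factor variance absorbs 1 - gamma^2
  }
  list(L = L, Phi = Phi, gamma = gamma)
}

wls_implied <- function(theta, lay) {
  par <- wls_unpack(theta, lay)
  S <- par$L %*% par$Phi %*% t(par$L)
  out <- S[lower.tri(S)]
  if (lay$n_exo > 0L) out <- c(out, as.vector(par$L %*% par$gamma))
  out
}

wls_jacobian <- function(theta, lay) {
  spec <- lay$spec
  par <- wls_unpack(theta, lay)
  L <- par$L; Phi <- par$Phi; gamma <- par$gamma
  A <- lay$pairA; B <- lay$pairB
  d <- lay$d1 + (if (lay$n_exo > 0L) lay$J else 0L)
  Jac <- matrix(0, d, lay$n_theta)
  BP <- L %*% Phi
  col <- 0L
  for (k in seq_len(spec$n_free_loadings)) {
    col <- col + 1L
    i <- spec$load_idx[k, 1L]; f <- spec$load_idx[k, 2L]
    ri <- lay$rows_of_item[[i]]
    Jac[ri$rows, col] <- BP[ri$partner, f]
    if (lay$n_exo > 0L) Jac[lay$d1 + i, col] <- gamma[f]
  }
  for (k in seq_len(spec$n_free_phi)) {
    col <- col + 1L
    f <- spec$phi_free[k, 1L]; g <- spec$phi_free[k, 2L]
    Jac[seq_len(lay$d1), col] <- L[A, f] * L[B, g] + L[A, g] * L[B, f]
  }
  if (lay$n_gamma > 0L) {
    cc <- as.vector(L %*% gamma)
    for (f in seq_len(lay$F)) {
      col <- col + 1L
      Jac[seq_len(lay$d1), col] <- L[A, f] * cc[B] + cc[A] * L[B, f] -
        2 * gamma[f] * L[A, f] * L[B, f]
      Jac[lay$d1 + seq_len(lay$J), col] <- L[, f]
    }
  }
  Jac
}

wls_start <- function(lay) {
  spec <- lay$spec
  load0 <- if (spec$structure == "bifactor")
    c(rep(0.5, lay$J), rep(0.35, lay$J)) else rep(0.5, lay$J)
  c(load0, rep(0.3, spec$n_free_phi), rep(0, lay$n_gamma))
}

# clamp item communalities away from 1 (Heywood guard); returns theta
wls_clamp <- function(theta, lay, limit = 0.999) {
  par <- wls_unpack(theta, lay)
  comm <- rowSums((par$L %*% par$Phi) * par$L)
  over <- which(comm > limit)
  if (length(over) > 0L) {
    nl <- lay$spec$n_free_loadings
    li <- lay$spec$load_idx
    for (i in over) {
      sel <- which(li[, 1L] == i)
      theta[sel] <- theta[sel] * sqrt(limit / comm[i])
    }
    attr(theta, "heywood") <- lay$spec$item_names[over]
  }
  theta
}

# Levenberg-damped Gauss-Newton minimization of sum(w * (s - sigma)^2).
wls_engine <- function(s_obs, w, lay, start = NULL, max_iter = 500L,
                       grad_tol = 1e-6, on_nonconvergence = c("error",
                                                              "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  theta <- if (is.null(start)) wls_start(lay) else start
  heywood <- character(0)
  fval <- function(th) {
    r <- s_obs - wls_implied(th, lay)
    sum(w * r^2)
  }
  f0 <- fval(theta)
  damp <- 1e-4
  iter <- 0L
  gnorm <- Inf
  stalled <- 0L
  at_boundary <- FALSE
  # the objective is weighted by inverse sampling variances, so the
  # gradient scales with mean(w); the tolerance follows that scale
  gtol_eff <- grad_tol * max(1, mean(w))
  repeat {
    iter <- iter + 1L
    Jac <- wls_jacobian(theta, lay)
    r <- s_obs - wls_implied(theta, lay)
    g <- crossprod(Jac, w * r)          # -(1/2) gradient of f
    gnorm <- 2 * sqrt(sum(g^2))
    if (gnorm < gtol_eff || iter > max_iter || stalled >= 3L) break
    A <- crossprod(Jac * sqrt(w))
    accepted <- FALSE
    for (try in 1:40) {
      step <- tryCatch(solve(A + damp * diag(diag(A) + 1e-10), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- wls_clamp(theta + as.vector(step), lay)
        at_boundary <- !is.null(attr(cand, "heywood"))
        if (at_boundary)
          heywood <- union(heywood, attr(cand, "heywood"))
        f1 <- fval(cand)
        if (is.finite(f1) && f1 <= f0 + 1e-12) {
          stalled <- if (f0 - f1 < 1e-12 * (1 + abs(f0))) stalled + 1L
                     else 0L
          theta <- as.vector(cand)
          f0 <- f1
          damp <- max(damp / 3, 1e-10)
          accepted <- TRUE
          break
        }
      }
      damp <- damp * 10
    }
    if (!accepted) { stalled <- 3L; break }  # no further descent possible
  }
  # a stall at an active communality boundary is a constrained optimum,
  # not an optimizer failure; a stall elsewhere with a near-zero gradient
  # is numerical convergence within the precision of the damped iteration
  converged <- gnorm < gtol_eff || f0 < 1e-14 ||
    (stalled >= 3L && (at_boundary || gnorm < 1e3 * gtol_eff))
  if (!converged) {
    msg <- sprintf("DWLS did not converge after %d iterations (gradient norm %.3g)",
                   iter, gnorm)
    if (on_nonconvergence == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  # report only items constrained at the boundary in the final solution
  par_fin <- wls_unpack(theta, lay)
  comm_fin <- rowSums((par_fin$L %*% par_fin$Phi) * par_fin$L)
  heywood <- lay$spec$item_names[comm_fin >= 0.999 - 1e-8]
  if (length(heywood) > 0L)
    warnf("Heywood case: communality constrained at the boundary for item(s) %s",
          paste(heywood, collapse = ", "))
  list(theta = theta, discrepancy = f0, gradient_norm = gnorm,
       iterations = iter, converged = converged, heywood = heywood)
}

# Satterthwaite mean-variance adjustment traces given the influence matrix.
# Cov = crossprod(psi)/wtot^2 estimates the sampling covariance of the
# moment vector; U = W - W D (D' W D)^{-1} D' W.
wls_adjust <- function(psi, wtot, w, Jac, T_raw) {
  Cov <- crossprod(psi) / wtot^2
  WD <- Jac * w
  A <- crossprod(Jac * sqrt(w))
  M <- w * Cov - WD %*% solve(A, crossprod(WD, Cov))
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  # baseline (independence) model: U = W
  Mb <- w * Cov
  tr1_b <- sum(diag(Mb))
  tr2_b <- sum(Mb * t(Mb))
  scale <- tr2 / tr1
  scale_b <- tr2_b / tr1_b
  list(chisq = T_raw / scale, df = tr1^2 / tr2, scale = scale,
       baseline_scale = scale_b, baseline_df = tr1_b^2 / tr2_b)
}

#' Fit a measurement structure by diagonally weighted least squares
#'
#' Minimizes the inverse-asymptotic-variance weighted sum of squared
#' differences between the observed polychoric correlations and the
#' model-implied correlations (thresholds fixed at their univariate
#' estimates; factor variances fixed to 1; delta parameterization, so
#' loadings are standardized and residual variances are
#' `1 - communality`). The test statistic is mean-and-variance
#' (Satterthwaite) adjusted using the asymptotic covariance of the
#' polychoric vector assembled from per-observation influence functions;
#' the adjusted degrees of freedom are estimated, not the naive moment
#' count.
#'
#' @param poly a [polychoric_matrix()] summary (with influence when
#'   `adjust = TRUE`).
#' @param spec a [build_model()] specification.
#' @param n sample size used for reporting; defaults to the polychoric
#'   summary's total weight.
#' @param adjust compute the adjusted chi-square (and baseline statistics
#'   for incremental fit indices).
#' @param se compute sandwich standard errors for the free parameters.
#' @param start,max_iter,grad_tol,on_nonconvergence optimizer controls;
#'   convergence requires gradient norm `< grad_tol`.
#' @return object of class `measurement_fit`: standardized `loadings`
#'   (item x factor), `phi` (factor correlations), `thresholds`,
#'   `residual_variance`, `discrepancy`, adjusted `chisq`/`df`, naive
#'   `df_naive`, `baseline` statistics, `n_parameters` (loadings +
#'   thresholds + factor correlations), convergence diagnostics.
#' @export
fit_dwls <- function(poly, spec, n = NULL, adjust = TRUE, se = FALSE,
                     start = NULL, max_iter = 500L, grad_tol = 1e-6,
                     on_nonconvergence = "error") {
  stopifnot(inherits(poly, "polychoric_summary"),
            inherits(spec, "model_spec"))
  if (length(poly$thresholds) != spec$n_items)
    stopf("polychoric summary has %d items but spec has %d",
          length(poly$thresholds), spec$n_items)
  lay <- wls_layout(spec, n_exo = 0L)
  s_obs <- poly$R[lower.tri(poly$R)]
  w <- 1 / pmax(poly$avar, 1e-10)
  fit <- wls_engine(s_obs, w, lay, start, max_iter, grad_tol,
                    on_nonconvergence)
  par <- wls_unpack(fit$theta, lay)
  comm <- rowSums((par$L %*% par$Phi) * par$L)
  n_thresh <- sum(lengths(poly$thresholds))
  p_struct <- lay$n_theta
  d <- lay$d1
  if (is.null(n)) n <- poly$wtot
  T_raw <- fit$discrepancy
  T_b_raw <- sum(w * s_obs^2)
  out <- list(
    spec = spec, structure = spec$structure,
    loadings = par$L, phi = par$Phi,
    thresholds = poly$thresholds,
    residual_variance = setNames(1 - comm, spec$item_names),
    discrepancy = T_raw,
    chisq = T_raw, df = d - p_struct, df_naive = d - p_struct,
    chisq_scale = 1,
    baseline = list(chisq = T_b_raw, df = d),
    n = n, wtot = poly$wtot,
    n_parameters = p_struct + n_thresh,
    n_structural_parameters = p_struct,
    converged = fit$converged, gradient_norm = fit$gradient_norm,
    iterations = fit$iterations, heywood = fit$heywood,
    rmsea_n_convention = "total weight (n), not n - 1"
  )
  if (adjust) {
    if (is.null(poly$influence))
      stopf("adjust = TRUE needs a polychoric summary with influence = TRUE")
    Jac <- wls_jacobian(fit$theta, lay)
    adj <- wls_adjust(poly$influence, poly$wtot, w, Jac, T_raw)
    out$chisq <- adj$chisq
    out$df <- adj$df
    out$chisq_scale <- adj$scale
    out$baseline <- list(chisq = T_b_raw / adj$baseline_scale,
                         df = adj$baseline_df)
  }
  if (se) {
    if (is.null(poly$influence))
      stopf("se = TRUE needs a polychoric summary with influence = TRUE")
    Jac <- wls_jacobian(fit$theta, lay)
    A <- crossprod(Jac * sqrt(w))
    P <- (poly$influence / poly$wtot) %*% (Jac * w)
    acov <- solve(A, crossprod(P)) %*% solve(A)
    out$theta <- fit$theta
    out$theta_se <- sqrt(pmax(diag(acov), 0))
  }
  class(out) <- "measurement_fit"
  out
}

#' @export
print.measurement_fit <- function(x, ...) {
  cat(sprintf("DWLS fit, %s structure: chi^2(adj) = %.2f on %.1f df, discrepancy %.4g\n",
              x$structure, x$chisq, x$df, x$discrepancy))
  cat(sprintf("%d free structural parameters (+%d thresholds), converged: %s\n",
              x$n_structural_parameters,
              x$n_parameters - x$n_structural_parameters, x$converged))
  invisible(x)
}

#' Absolute and incremental fit indices for a DWLS fit
#'
#' RMSEA with a 90 percent confidence interval by noncentral chi-square
#' root finding, CFI and TLI against the independence baseline (free
#' thresholds, zero correlations) fitted on the same moments. The RMSEA
#' denominator uses n (the total weight), a convention recorded in the
#' output.
#'
#' @param fitted a [fit_dwls()] result (fitted with `adjust = TRUE` for
#'   adjusted statistics).
#' @param baseline optional baseline fit; defaults to the independence
#'   statistics stored in `fitted`.
#' @param n sample size; defaults to `fitted$n`.
#' @param ci_level confidence level for the RMSEA interval.
#' @return object of class `fit_indices`: `rmsea`, `rmsea_ci`, `cfi`,
#'   `tli`, `chisq`, `df`, `formatted` (e.g. `"0.029 (0.028, 0.030)"`).
#' @export
compute_fit_indices <- function(fitted, baseline = NULL, n = NULL,
                                ci_level = 0.90) {
  chisq <- fitted$chisq; df <- fitted$df
  if (is.null(n)) n <- fitted$n
  if (is.null(baseline)) {
    cb <- fitted$baseline$chisq; dfb <- fitted$baseline$df
  } else {
    cb <- baseline$chisq; dfb <- baseline$df
  }
  undefined <- df <= 0
  if (undefined) {
    rmsea <- 0; lo <- 0; hi <- 0
  } else {
    rmsea <- sqrt(max(chisq - df, 0) / (df * n))
    alpha <- (1 - ci_level) / 2
    ncp_root <- function(target) {
      # largest ncp with pchisq(chisq, df, ncp) >= target
      if (pchisq(chisq, df) < target) return(0)
      f <- function(l) pchisq(chisq, df, ncp = l) - target
      upper <- max(chisq * 2, df * 2, 10)
      while (f(upper) > 0) upper <- upper * 2
      uniroot(f, c(0, upper), tol = 1e-8)$root
    }
    lo <- sqrt(ncp_root(1 - alpha) / (df * n))
    hi <- sqrt(ncp_root(alpha) / (df * n))
  }
  num <- max(chisq - df, 0)
  den <- max(cb - dfb, chisq - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli <- if (dfb > 0 && df > 0 && (cb / dfb) != 1)
    ((cb / dfb) - (chisq / df)) / ((cb / dfb) - 1) else 1
  structure(list(
    rmsea = rmsea, rmsea_ci = c(lower = lo, upper = hi),
    cfi = cfi, tli = tli, chisq = chisq, df = df,
    baseline_chisq = cb, baseline_df = dfb, n = n,
    rmsea_undefined = undefined,
    formatted = format_ci3(rmsea, lo, hi)
  ), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("RMSEA %s  CFI %.3f  TLI %.3f  (chi^2 %.2f, df %.1f)\n",
              x$formatted, x$cfi, x$tli, x$chisq, x$df))
  invisible(x)
}

#' Information criteria from the marginal ordinal likelihood
#'
#' Evaluates the marginal likelihood of the ordinal responses, integrating
#' over the latent factors by randomized quasi-Monte Carlo (seeded
#' randomly-shifted Halton nodes), at the limited-information parameter
#' estimates, and reports AIC, BIC and sample-size-adjusted BIC with the
#' fit's full parameter count (loadings + thresholds + factor
#' correlations).
#'
#' @param items integer item matrix (categories `0..K-1`, NA marginalized
#'   per respondent).
#' @param fitted a [fit_dwls()] (or structural) fit supplying loadings,
#'   thresholds, residual variances and factor correlations.
#' @param n_points number of integration points (>= 500; default 8000).
#' @param seed integer seed for the node randomization.
#' @return object of class `ic_fit`: `logLik`, `aic`, `bic`, `ssa_bic`,
#'   `n_parameters`, `n`, `n_points`, `seed`.
#' @export
fit_marginal_ml <- function(items, fitted, n_points = 8000L, seed = 1L) {
  if (!is_count(n_points) || n_points < 500L)
    stopf("n_points must be a count >= 500")
  L <- fitted$loadings
  F <- ncol(L)
  if (n_points < 250L * F)
    warnf("n_points = %d is small for %d factors; criteria may be noisy",
          n_points, F)
  items <- as.matrix(items)
  if (ncol(items) != nrow(L))
    stopf("items have %d columns but the fit has %d items", ncol(items),
          nrow(L))
  y <- items
  storage.mode(y) <- "integer"
  y[is.na(y)] <- -1L
  rs <- sqrt(pmax(fitted$residual_variance, 1e-8))
  nodes <- halton_normal(n_points, F, seed)
  ch <- tryCatch(chol(fitted$phi), error = function(e)
    stopf("factor correlation matrix is not positive definite"))
  nodes <- nodes %*% ch
  ll_i <- .qmc_loglik_cpp(y, L, unname(fitted$thresholds), rs, nodes)
  ll <- sum(ll_i)
  p <- fitted$n_parameters
  n <- nrow(items)
  structure(list(
    logLik = ll, n_parameters = p, n = n, n_points = n_points, seed = seed,
    aic = -2 * ll + 2 * p,
    bic = -2 * ll + p * log(n),
    ssa_bic = -2 * ll + p * log((n + 2) / 24)
  ), class = "ic_fit")
}

#' @export
print.ic_fit <- function(x, ...) {
  cat(sprintf("Marginal ordinal likelihood: logLik %.1f (p = %d, n = %d, %d QMC points)\n",
              x$logLik, x$n_parameters, x$n, x$n_points))
  cat(sprintf("AIC %.1f  BIC %.1f  ssaBIC %.1f\n", x$aic, x$bic, x$ssa_bic))
  invisible(x)
}

#' Filter respondents by answered items per block
#'
#' Keeps respondents with at least `min_per_block` non-missing responses in
#' every instrument block (default 4), the inclusion rule for association
#' analyses.
#'
#' @param items item matrix with a `"blocks"` attribute (or supply
#'   `blocks`).
#' @param min_per_block minimum answered items per block; 0 keeps everyone.
#' @param blocks optional character vector of per-item block labels.
#' @return the filtered matrix; attribute `"filter_report"` holds counts
#'   (respondents before/after, exclusions per block).
#' @export
apply_inclusion_filter <- function(items, min_per_block = 4L,
                                   blocks = NULL) {
  if (is.null(blocks)) blocks <- attr(items, "blocks")
  if (is.null(blocks)) stopf("no block assignment found")
  bl <- unique(blocks)
  answered <- sapply(bl, function(b)
    rowSums(!is.na(items[, blocks == b, drop = FALSE])))
  if (is.null(dim(answered))) answered <- matrix(answered, nrow = 1L)
  keep <- rowSums(answered >= min_per_block) == length(bl)
  out <- items[keep, , drop = FALSE]
  attr(out, "blocks") <- blocks
  attr(out, "filter_report") <- list(
    n_before = nrow(items), n_after = sum(keep),
    min_per_block = min_per_block,
    failing_per_block = colSums(answered < min_per_block))
  out
}
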