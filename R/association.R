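# Structural (MIMIC) association analysis: every latent factor regressed
# simultaneously on a standardized polygenic score within the correlated
# or bifactor measurement structure, with sandwich standard errors,
# permutation family-wise adjusted p-values on factor scores, and
# inverse-probability weighting for selective missingness.

prs_vector <- function(prs) {
  if (inherits(prs, "polygenic_score")) {
    if (is.null(prs$z)) stopf("polygenic score is not standardized")
    setNames(prs$z, prs$id)
  } else if (is.numeric(prs)) {
    prs
  } else stopf("prs must be a polygenic_score or a numeric vector")
}

#' Simultaneous latent-factor-on-PRS regression (MIMIC model)
#'
#' Extends the measurement model with a structural part regressing every
#' latent factor on one standardized exposure: the moment vector stacks
#' the item-item polychoric correlations and the item-exposure polyserial
#' correlations, and diagonally weighted least squares estimates loadings,
#' residual factor correlations (correlated structure) and the
#' standardized regression coefficients (SD of factor per SD of exposure)
#' jointly. Standard errors are sandwich estimates from the influence
#' functions of the correlation vector; Wald confidence intervals and
#' p-values follow.
#'
#' @param items item matrix (categories `0..K-1`, NA allowed), respondent
#'   ids in rownames.
#' @param prs a `polygenic_score` or a named standardized numeric vector.
#' @param spec a [build_model()] spec with structure `"correlated"` or
#'   `"bifactor"`.
#' @param weights optional named inverse-probability case weights
#'   (respondent ids in names, or an [estimate_ipw()] result).
#' @param conf_level Wald confidence level (default 0.95).
#' @param adjust also compute the adjusted chi-square of the structural
#'   model (slower; off by default).
#' @param ... further arguments to the optimizer (see [fit_dwls()]).
#' @return object of class `structural_fit`: `table` (one row per factor:
#'   `outcome`, `beta`, `se`, `lci`, `uci`, `p`), `model`, `n_analyzed`,
#'   plus the fitted measurement quantities (`loadings`, `phi`,
#'   `thresholds`, `residual_variance`).
#' @export
fit_structural <- function(items, prs, spec, weights = NULL,
                           conf_level = 0.95, adjust = FALSE, ...) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$structure %in% c("correlated", "bifactor"))
    stopf("structural model requires the correlated or bifactor structure")
  x <- prs_vector(prs)
  ids <- rownames(items)
  if (is.null(ids) || is.null(names(x)))
    stopf("items rownames and score ids are both required to match respondents")
  common <- intersect(ids, names(x))
  if (length(common) < 10L)
    stopf("fewer than 10 respondents match between items and scores (%d)",
          length(common))
  items_m <- items[common, , drop = FALSE]
  x <- x[common]
  x <- (x - mean(x)) / sd(x)  # (re)standardize within the analysis sample
  w <- NULL
  if (!is.null(weights)) {
    if (inherits(weights, "ipw_weights")) {
      weights <- setNames(weights$weight, weights$id)
    }
    if (is.null(names(weights)))
      stopf("weights must be named by respondent id")
    miss_w <- setdiff(common, names(weights))
    if (length(miss_w) > 0)
      stopf("no weight for %d analyzed respondent(s)", length(miss_w))
    w <- as.numeric(weights[common])
    if (any(!is.finite(w)) || any(w <= 0))
      stopf("weights must be positive and finite")
    w <- w * length(w) / sum(w)  # scale invariance: mean-1 normalization
  }

  poly <- polychoric_matrix(items_m, weights = w, influence = TRUE)
  ps <- lapply(seq_len(ncol(items_m)), function(j)
    estimate_polyserial(x, items_m[, j], weights = w))
  s_obs <- c(poly$R[lower.tri(poly$R)], vapply(ps, `[[`, 0, "rho"))
  avar <- c(poly$avar, vapply(ps, `[[`, 0, "avar"))
  wls_w <- 1 / pmax(avar, 1e-10)
  psi <- cbind(poly$influence, sapply(ps, `[[`, "influence"))

  lay <- wls_layout(spec, n_exo = 1L)
  fit <- wls_engine(s_obs, wls_w, lay, ...)
  par <- wls_unpack(fit$theta, lay)
  Jac <- wls_jacobian(fit$theta, lay)
  A <- crossprod(Jac * sqrt(wls_w))
  P <- (psi / poly$wtot) %*% (Jac * wls_w)
  acov <- solve(A, crossprod(P)) %*% solve(A)
  se_all <- sqrt(pmax(diag(acov), 0))
  gsel <- lay$n_theta - lay$F + seq_len(lay$F)
  beta <- par$gamma
  se <- se_all[gsel]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  pv <- 2 * pnorm(-abs(beta / se))
  tab <- data.frame(outcome = spec$factor_names, beta = beta, se = se,
                    lci = beta - zq * se, uci = beta + zq * se,
                    p = pmax(pv, .Machine$double.xmin),
                    stringsAsFactors = FALSE)
  comm <- rowSums((par$L %*% par$Phi) * par$L)
  out <- list(
    table = tab, model = spec$structure, n_analyzed = length(common),
    structure = spec$structure, spec = spec,
    loadings = par$L, phi = par$Phi, gamma = par$gamma,
    thresholds = poly$thresholds,
    residual_variance = setNames(1 - comm, spec$item_names),
    n_parameters = lay$n_theta + sum(lengths(poly$thresholds)),
    theta = fit$theta, theta_se = se_all, acov = acov,
    converged = fit$converged, gradient_norm = fit$gradient_norm,
    heywood = fit$heywood, weighted = !is.null(w),
    conf_level = conf_level, ids = common
  )
  if (adjust) {
    adj <- wls_adjust(psi, poly$wtot, wls_w, Jac, fit$discrepancy)
    out$chisq <- adj$chisq
    out$df <- adj$df
  }
  class(out) <- "structural_fit"
  out
}

#' @export
print.structural_fit <- function(x, ...) {
  cat(sprintf("Structural (%s) model, n = %d%s\n", x$model, x$n_analyzed,
              if (x$weighted) ", inverse-probability weighted" else ""))
  tab <- x$table
  tab$beta <- sprintf("% .3f", tab$beta)
  tab$lci <- sprintf("% .3f", tab$lci)
  tab$uci <- sprintf("% .3f", tab$uci)
  tab$p <- sprintf("%.3g", tab$p)
  print(tab[, c("outcome", "beta", "lci", "uci", "p")], row.names = FALSE)
  invisible(x)
}

#' Maximum a posteriori factor scores under the ordinal measurement model
#'
#' Mode of the latent posterior given each respondent's observed
#' categories (missing items marginalized), found by per-respondent Newton
#' iteration with step halving; the prior is the fitted factor correlation
#' matrix. Respondents with no observed responses get missing scores.
#'
#' @param fitted a [fit_dwls()] or [fit_structural()] result.
#' @param items item matrix matching the fit's items.
#' @return respondent x factor matrix of scores (rownames preserved),
#'   with attribute `"converged"`.
#' @export
estimate_factor_scores <- function(fitted, items) {
  if (!isTRUE(fitted$converged))
    stopf("measurement model did not converge; refusing to score")
  items <- as.matrix(items)
  L <- fitted$loadings
  if (ncol(items) != nrow(L))
    stopf("items have %d columns but the fit has %d items",
          ncol(items), nrow(L))
  y <- items
  storage.mode(y) <- "integer"
  y[is.na(y)] <- -1L
  rs <- sqrt(pmax(fitted$residual_variance, 1e-8))
  res <- .map_scores_cpp(y, L, unname(fitted$thresholds), rs,
                         solve(fitted$phi), 100L, 1e-8)
  sc <- res$scores
  dimnames(sc) <- list(rownames(items), colnames(L))
  attr(sc, "converged") <- res$converged
  sc
}

#' Permutation family-wise adjusted p-values (max-T, step-down)
#'
#' Permutes the exposure vector jointly against all factor-score outcomes
#' (preserving the inter-factor correlation), recomputes each
#' score-on-exposure regression t statistic, and applies Westfall-Young
#' step-down max-T adjustment: each observed |t| is compared with the
#' permutation distribution of the running maximum over the hypotheses not
#' yet rejected, with `p = (1 + exceedances) / (1 + n_perm)` and enforced
#' monotonicity. With a single outcome this reduces to the unadjusted
#' permutation p-value.
#'
#' @param scores respondent x outcome matrix of factor scores.
#' @param prs exposure: `polygenic_score` or numeric vector (matched by
#'   names/rownames when present, else positionally).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (fixed seed gives bit-identical p-values).
#' @return object of class `permutation_result`: data.frame (`outcome`,
#'   `t`, `p_unadjusted`, `p_adjusted`) plus `n_perm`, `seed`, `n`.
#' @export
permutation_adjusted_p <- function(scores, prs, n_perm = 1000L, seed = 1L) {
  if (!is_count(n_perm) || n_perm < 100L)
    stopf("n_perm must be a count >= 100")
  scores <- as.matrix(scores)
  x <- prs_vector(prs)
  if (!is.null(names(x)) && !is.null(rownames(scores))) {
    common <- intersect(rownames(scores), names(x))
    scores <- scores[common, , drop = FALSE]
    x <- x[common]
  } else if (length(x) != nrow(scores)) {
    stopf("scores and exposure differ in length and carry no ids")
  }
  ok <- complete.cases(scores) & !is.na(x)
  scores <- scores[ok, , drop = FALSE]
  x <- x[ok]
  n <- length(x)
  if (sd(x) < 1e-12) stopf("constant exposure: permutation test undefined")
  K <- ncol(scores)
  t_of <- function(xv) {
    r <- suppressWarnings(cor(xv, scores))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    as.vector(r * sqrt((n - 2) / (1 - r^2)))
  }
  t_obs <- t_of(x)
  Tperm <- with_seed(seed, {
    out <- matrix(0, n_perm, K)
    chunk <- 250L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      Pm <- vapply(seq_len(b), function(i) x[sample.int(n)], numeric(n))
      r <- suppressWarnings(cor(Pm, scores))
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      out[done + seq_len(b), ] <- r * sqrt((n - 2) / (1 - r^2))
      done <- done + b
    }
    out
  })
  abs_t <- abs(t_obs)
  abs_perm <- abs(Tperm)
  p_unadj <- vapply(seq_len(K), function(k)
    (1 + sum(abs_perm[, k] >= abs_t[k])) / (1 + n_perm), numeric(1))
  # step-down max-T over hypotheses ordered by decreasing |t|
  ord <- order(abs_t, decreasing = TRUE)
  p_adj <- numeric(K)
  running_max <- rep(-Inf, n_perm)
  for (j in rev(seq_len(K))) {  # from smallest |t|: accumulate the max
    k <- ord[j]
    running_max <- pmax(running_max, abs_perm[, k])
    p_adj[k] <- (1 + sum(running_max >= abs_t[k])) / (1 + n_perm)
  }
  if (K > 1) {  # enforce monotonicity down the rejection order
    for (j in 2:K)
      p_adj[ord[j]] <- max(p_adj[ord[j]], p_adj[ord[j - 1]])
  }
  p_adj <- pmax(p_adj, p_unadj)
  structure(list(
    table = data.frame(outcome = colnames(scores) %||% paste0("F", 1:K),
                       t = t_obs, p_unadjusted = p_unadj,
                       p_adjusted = p_adj, stringsAsFactors = FALSE),
    n_perm = n_perm, seed = seed, n = n
  ), class = "permutation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Max-T step-down permutation adjustment: %d permutations, n = %d, seed %d\n",
              x$n_perm, x$n, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Inverse-probability weights for selective inclusion
#'
#' Fits a logistic model of the inclusion indicator on auxiliary
#' covariates observed for included and excluded respondents, and returns
#' `1 / p-hat` weights for the included, optionally truncated at a weight
#' quantile (default the 99th percentile; truncation is flagged).
#'
#' @param included logical inclusion indicator for all respondents.
#' @param covariates data.frame of auxiliary covariates (all respondents,
#'   same order); respondent ids in an `id` column or rownames.
#' @param truncate_at weight-quantile for truncation in (0, 1], or `NULL`
#'   for none.
#' @return object of class `ipw_weights`: data.frame over included
#'   respondents (`id`, `probability`, `weight`, `truncated`), with the
#'   fitted inclusion model in attribute `"model"`.
#' @export
estimate_ipw <- function(included, covariates, truncate_at = 0.99) {
  covariates <- as.data.frame(covariates)
  ids <- if ("id" %in% names(covariates)) as.character(covariates$id)
         else rownames(covariates)
  covs <- covariates[, setdiff(names(covariates), "id"), drop = FALSE]
  if (length(included) != nrow(covs))
    stopf("included and covariates differ in length")
  dat <- cbind(.included = as.numeric(included), covs)
  fit <- suppressWarnings(glm(.included ~ ., data = dat,
                              family = binomial()))
  ph <- fitted(fit)
  cf <- coef(fit)[-1]
  # separation: a diverging slope, or an included respondent whose
  # modelled inclusion probability is numerically zero
  if (!fit$converged || any(abs(cf) > 15) || any(ph[included] < 1e-8)) {
    worst <- names(cf)[which.max(abs(cf))]
    stopf("separation in the inclusion model (covariate '%s'); cannot weight",
          worst)
  }
  sel <- which(included)
  wgt <- 1 / ph[sel]
  truncated <- rep(FALSE, length(sel))
  if (!is.null(truncate_at)) {
    cap <- quantile(wgt, truncate_at, names = FALSE)
    truncated <- wgt > cap
    wgt[truncated] <- cap
  }
  out <- data.frame(id = ids[sel], probability = ph[sel], weight = wgt,
                    truncated = truncated, stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  attr(out, "truncate_at") <- truncate_at
  class(out) <- c("ipw_weights", "data.frame")
  out
}

#' Inverse-probability weighted structural model
#'
#' Refits the structural (MIMIC) model with every estimating equation
#' weighted by the inverse inclusion probabilities: thresholds, polychoric
#' and polyserial correlations are weighted, and the sandwich standard
#' errors propagate the weights. With all weights equal to 1 the result is
#' identical to the unweighted fit; point estimates are invariant to
#' rescaling the weights.
#'
#' @param items,prs,spec as in [fit_structural()].
#' @param weights an [estimate_ipw()] result or named weight vector.
#' @param ... passed to [fit_structural()].
#' @return a `structural_fit` (with `weighted = TRUE`).
#' @export
weighted_structural <- function(items, prs, spec, weights, ...) {
  if (is.null(weights)) stopf("weights are required; use fit_structural otherwise")
  fit_structural(items, prs, spec, weights = weights, ...)
}
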