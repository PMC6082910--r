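# Model specification, DWLS fitting, fit indices, marginal-likelihood
# information criteria and the inclusion filter.

test_that("parameter accounting distinguishes the four structures", {
  tm <- true_model()
  blocks <- setNames(tm$blocks, tm$item_names)
  poly <- population_poly(truth_corr(tm), tm$thresholds)
  counts <- sapply(c("uncorrelated", "unidimensional", "correlated",
                     "bifactor"),
                   function(st) fit_dwls(poly, build_model(st, blocks),
                                         adjust = FALSE)$n_parameters)
  # bifactor adds one general loading per item; correlated adds the six
  # factor correlations; unidimensional and uncorrelated count equally
  expect_identical(unname(counts["bifactor"] - counts["uncorrelated"]), 51L)
  expect_identical(unname(counts["correlated"] - counts["uncorrelated"]), 6L)
  expect_identical(unname(counts["unidimensional"]),
                   unname(counts["uncorrelated"]))
  expect_error(build_model("hierarchical", blocks), "unknown structure")
})

test_that("DWLS recovers generating parameters from population moments", {
  # single-factor closed form: implied Sigma = lambda lambda^T + diag resid
  lam <- c(0.6, 0.7, 0.8, 0.5, 0.65)
  R <- tcrossprod(lam); diag(R) <- 1
  colnames(R) <- rownames(R) <- paste0("it", 1:5)
  taus <- setNames(rep(list(qnorm(c(0.6, 0.9))), 5), colnames(R))
  poly <- population_poly(R, taus)
  spec <- build_model("unidimensional",
                      setNames(rep("PE", 5), colnames(R)))
  f <- fit_dwls(poly, spec, adjust = FALSE)
  expect_lt(max(abs(f$loadings[, 1] - lam)), 1e-4)
  expect_lt(f$discrepancy, 1e-10)
  expect_identical(unname(f$thresholds[[1]]), qnorm(c(0.6, 0.9)))
})

test_that("the adjusted statistic is calibrated when fitting the truth", {
  tm <- true_model()
  blocks <- setNames(tm$blocks, tm$item_names)
  eta <- simulate_factors(NULL, zero_betas(), n = 20000, seed = 71)
  y <- simulate_item_responses(eta, tm, seed = 72)
  poly <- polychoric_matrix(y)
  f <- fit_dwls(poly, build_model("bifactor", blocks), adjust = TRUE)
  expect_true(f$converged)
  expect_lt(abs(f$chisq / f$df - 1), 0.25)
  expect_lt(f$df, f$df_naive)  # estimated df, not the naive moment count

  fi <- compute_fit_indices(f)
  expect_lt(fi$rmsea, 0.01)
  expect_gt(fi$cfi, 0.995)
  expect_gt(fi$tli, 0.995)
})

test_that("fit indices respect their formula boundaries and format", {
  fake <- list(chisq = 100, df = 100, baseline = list(chisq = 500, df = 120),
               n = 1000)
  fi <- compute_fit_indices(fake)
  expect_equal(fi$rmsea, 0)  # chi-square equal to df

  # model as bad as the baseline: CFI collapses to zero
  fake2 <- list(chisq = 500, df = 120, baseline = list(chisq = 500, df = 120),
                n = 1000)
  expect_equal(compute_fit_indices(fake2)$cfi, 0)

  # df = 0: undefined RMSEA reported as 0 with a flag
  fake3 <- list(chisq = 5, df = 0, baseline = list(chisq = 50, df = 10),
                n = 1000)
  fi3 <- compute_fit_indices(fake3)
  expect_equal(fi3$rmsea, 0)
  expect_true(fi3$rmsea_undefined)

  # three-decimal reporting with a 90% interval
  fake4 <- list(chisq = 300, df = 150, baseline = list(chisq = 5e4, df = 200),
                n = 3650)
  fi4 <- compute_fit_indices(fake4)
  expect_match(fi4$formatted,
               "^0\\.\\d{3} \\(0\\.\\d{3}, 0\\.\\d{3}\\)$")
  expect_lte(fi4$rmsea_ci["lower"], fi4$rmsea)
  expect_gte(fi4$rmsea_ci["upper"], fi4$rmsea)
})

test_that("misspecified structures show worse absolute fit", {
  # correlated-factors truth: the uncorrelated model must fit clearly
  # worse than the correlated one
  tm <- true_model(general_range = c(0, 0),
                   specific_range = c(0.55, 0.8), seed = 73)
  blocks <- setNames(tm$blocks, tm$item_names)
  Phi5 <- diag(5); Phi5[2:5, 2:5] <- 0.5; diag(Phi5) <- 1
  eta <- simulate_factors(NULL, zero_betas(), n = 3000, seed = 74,
                          factor_cor = Phi5)
  y <- simulate_item_responses(eta, tm, seed = 75)
  poly <- polychoric_matrix(y)
  f_unc <- fit_dwls(poly, build_model("uncorrelated", blocks))
  f_cor <- fit_dwls(poly, build_model("correlated", blocks))
  fi_unc <- compute_fit_indices(f_unc)
  fi_cor <- compute_fit_indices(f_cor)
  expect_gt(fi_unc$rmsea, fi_cor$rmsea)
  expect_lt(fi_unc$cfi, fi_cor$cfi)
  expect_lt(fi_cor$rmsea, 0.03)
  # recovered factor correlations near the generating 0.5
  expect_lt(max(abs(f_cor$phi[lower.tri(f_cor$phi)] - 0.5)), 0.06)
})

test_that("marginal likelihood matches the closed form and the AIC identity", {
  # one binary item, one factor: unstandardized loading a, threshold t on
  # the residual (theta) scale correspond to standardized
  # lambda = a/sqrt(1+a^2), tau = t/sqrt(1+a^2); the marginal success
  # probability is Phi(-t/sqrt(1+a^2)) = Phi(-tau)
  a <- 1.2; t_theta <- 0.7
  lam <- a / sqrt(1 + a^2); tau <- t_theta / sqrt(1 + a^2)
  fake <- list(loadings = matrix(lam, 1, 1), thresholds = list(tau),
               residual_variance = 1 - lam^2, phi = matrix(1, 1, 1),
               n_parameters = 2L, structure = "unidimensional")
  y <- matrix(c(0L, 1L), 2, 1)
  ic <- fit_marginal_ml(y, fake, n_points = 4000, seed = 1)
  exact <- log(pnorm(tau)) + log(1 - pnorm(tau))
  expect_lt(abs(ic$logLik - exact), 5e-4)
  expect_equal(ic$aic - (-2 * ic$logLik), 2 * ic$n_parameters)
  expect_equal(ic$ssa_bic - (-2 * ic$logLik),
               ic$n_parameters * log((ic$n + 2) / 24))
  expect_error(fit_marginal_ml(y, fake, n_points = 100), "n_points")
})

test_that("information criteria are invariant to item and respondent order", {
  tm <- true_model(n_items = c(3, 3, 3, 3), seed = 76)
  blocks <- setNames(tm$blocks, tm$item_names)
  eta <- simulate_factors(NULL, zero_betas(), n = 600, seed = 77)
  y <- simulate_item_responses(eta, tm, seed = 78)
  poly <- polychoric_matrix(y)
  f <- fit_dwls(poly, build_model("bifactor", blocks), adjust = FALSE)
  ic1 <- suppressWarnings(fit_marginal_ml(y, f, n_points = 1000, seed = 9))

  # respondent order
  perm <- with_seed_local(79, sample(nrow(y)))
  ic2 <- suppressWarnings(fit_marginal_ml(y[perm, ], f, n_points = 1000,
                                          seed = 9))
  expect_equal(ic2$logLik, ic1$logLik, tolerance = 1e-10)

  # item order (permute items together with the fitted parameters)
  iperm <- with_seed_local(80, sample(ncol(y)))
  f2 <- f
  f2$loadings <- f$loadings[iperm, ]
  f2$thresholds <- f$thresholds[iperm]
  f2$residual_variance <- f$residual_variance[iperm]
  ic3 <- suppressWarnings(fit_marginal_ml(y[, iperm], f2, n_points = 1000,
                                          seed = 9))
  expect_equal(ic3$logLik, ic1$logLik, tolerance = 1e-10)
})

test_that("the inclusion filter applies the answered-items rule", {
  tm <- true_model()
  eta <- simulate_factors(NULL, zero_betas(), n = 6, seed = 81)
  y <- simulate_item_responses(eta, tm, seed = 82)
  # respondent 2: only 3 answered negative-dimension items
  y[2, which(attr(y, "blocks") == "NEG")[-(1:3)]] <- NA
  # respondent 3: misses a full block
  y[3, attr(y, "blocks") == "DEP"] <- NA
  kept <- apply_inclusion_filter(y, 4)
  expect_identical(nrow(kept), 4L)
  rep <- attr(kept, "filter_report")
  expect_identical(rep$n_before, 6L)
  expect_identical(rep$n_after, 4L)

  # identity at min_per_block = 0; full completeness always kept
  expect_identical(nrow(apply_inclusion_filter(y, 0)), 6L)
})
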