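# Structural MIMIC fits, factor scores, permutation adjustment and
# inverse-probability weighting.

test_that("the structural fit reports one row per factor with valid CIs", {
  tm <- true_model()
  blocks <- setNames(tm$blocks, tm$item_names)
  d <- sim_items_prs(1200, tm, beta_g = 0.06, seed = 101)
  f <- fit_structural(d$items, d$prs, build_model("bifactor", blocks))
  expect_identical(f$table$outcome, c("GENERAL", "PE", "NEG", "DEP", "ANX"))
  expect_true(all(f$table$lci <= f$table$beta & f$table$beta <= f$table$uci))
  expect_true(all(f$table$p > 0 & f$table$p <= 1))
  expect_identical(f$n_analyzed, 1200L)

  fc <- fit_structural(d$items, d$prs, build_model("correlated", blocks))
  expect_identical(fc$table$outcome, c("PE", "NEG", "DEP", "ANX"))
  expect_error(fit_structural(d$items, d$prs,
                              build_model("unidimensional", blocks)),
               "correlated or bifactor")
})

test_that("a permuted exposure yields null betas", {
  tm <- true_model()
  blocks <- setNames(tm$blocks, tm$item_names)
  d <- sim_items_prs(1500, tm, beta_g = 0.06, seed = 105)
  x_perm <- with_seed_local(106, setNames(sample(d$prs), names(d$prs)))
  f <- fit_structural(d$items, x_perm, build_model("bifactor", blocks))
  expect_lt(max(abs(f$table$beta)), 0.08)  # ~3 SE at this n
})

test_that("betas rescale exactly with the exposure's SD", {
  tm <- true_model(n_items = c(4, 4, 4, 4), seed = 107)
  blocks <- setNames(tm$blocks, tm$item_names)
  d <- sim_items_prs(800, tm, beta_g = 0.1, seed = 108)
  f1 <- fit_structural(d$items, d$prs, build_model("correlated", blocks))
  # scaling the exposure changes nothing: it is re-standardized internally
  f2 <- fit_structural(d$items, d$prs * 3.7,
                       build_model("correlated", blocks))
  expect_equal(f2$table$beta, f1$table$beta, tolerance = 1e-6)
})

test_that("MAP factor scores are monotone, equivariant and handle missing", {
  # single strong item: extreme category pushes the score into the tail
  spec1 <- build_model("unidimensional", c(it1 = "PE"))
  f1 <- list(structure = "unidimensional", spec = spec1, converged = TRUE,
             loadings = matrix(0.95, 1, 1), thresholds = list(c(-1, 1)),
             residual_variance = 1 - 0.95^2, phi = matrix(1, 1, 1))
  y1 <- matrix(c(0L, 1L, 2L), 3, 1)
  s1 <- estimate_factor_scores(f1, y1)
  expect_true(s1[1] < s1[2] & s1[2] < s1[3])
  expect_lt(s1[1], -0.8); expect_gt(s1[3], 0.8)

  tm <- true_model()
  fit <- truth_as_fit(tm)
  d <- sim_items_prs(400, tm, beta_g = 0, seed = 111)
  sc <- estimate_factor_scores(fit, d$items)
  # respondent-order equivariance
  perm <- with_seed_local(112, sample(400))
  sc_p <- estimate_factor_scores(fit, d$items[perm, ])
  strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }
  expect_equal(strip(sc_p), strip(sc[perm, ]), tolerance = 1e-10)
  # all-missing respondents score as missing
  y_na <- d$items; y_na[1, ] <- NA
  sc_na <- estimate_factor_scores(fit, y_na)
  expect_true(all(is.na(sc_na[1, ])))
  expect_false(anyNA(sc_na[-1, ]))
})

test_that("MAP scores track the generating factors", {
  tm <- true_model()
  d <- sim_items_prs(5000, tm, beta_g = 0, seed = 113)
  sc <- estimate_factor_scores(truth_as_fit(tm), d$items)
  slope_g <- unname(coef(lm(sc[, "GENERAL"] ~ d$factors[, "GENERAL"]))[2])
  expect_gt(slope_g, 0.75)  # the general factor is well determined
  expect_gt(cor(sc[, "GENERAL"], d$factors[, "GENERAL"]), 0.85)
  for (k in 2:5) expect_gt(cor(sc[, k], d$factors[, k]), 0.5)
})

test_that("permutation adjustment is deterministic, monotone and exact for one outcome", {
  set.seed(121)
  n <- 300
  x <- setNames(rnorm(n), paste0("id", 1:n))
  sc <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(names(x), paste0("F", 1:4)))
  sc[, 1] <- sc[, 1] + 0.25 * x  # one real signal
  p1 <- permutation_adjusted_p(sc, x, n_perm = 300, seed = 7)
  p2 <- permutation_adjusted_p(sc, x, n_perm = 300, seed = 7)
  expect_identical(p1$table, p2$table)  # bit-identical under a fixed seed
  expect_true(all(p1$table$p_adjusted >= p1$table$p_unadjusted))
  expect_true(all(p1$table$p_adjusted >= 1 / (300 + 1)))

  # family of size one: adjusted equals unadjusted
  ps <- permutation_adjusted_p(sc[, 1, drop = FALSE], x, n_perm = 200,
                               seed = 8)
  expect_equal(ps$table$p_adjusted, ps$table$p_unadjusted)

  # invariance under monotone transformation of the scores
  p3 <- permutation_adjusted_p(cbind(exp(sc[, 1, drop = FALSE])), x,
                               n_perm = 200, seed = 8)
  expect_equal(rank(abs(p3$table$t)), rank(abs(ps$table$t)))

  expect_error(permutation_adjusted_p(sc, x * 0, n_perm = 200), "constant")
  expect_error(permutation_adjusted_p(sc, x, n_perm = 50), "n_perm")
})

test_that("IPW weights invert the modelled inclusion probability", {
  set.seed(131)
  n <- 2000
  covs <- data.frame(id = paste0("id", 1:n), sex = rbinom(n, 1, 0.5),
                     background = rnorm(n))
  # inclusion independent of the covariates: weights nearly constant
  inc <- rbinom(n, 1, 0.7) == 1
  w <- estimate_ipw(inc, covs)
  expect_lt(diff(range(w$weight)) / mean(w$weight), 0.25)
  expect_identical(nrow(w), sum(inc))

  # covariate-driven inclusion: weights = 1 / p-hat, truncated at the cap
  inc2 <- runif(n) < plogis(0.5 + 1.2 * covs$background)
  w2 <- estimate_ipw(inc2, covs, truncate_at = 0.95)
  expect_true(all(w2$weight > 0))
  expect_gte(mean(w2$truncated), 0)
  untrunc <- estimate_ipw(inc2, covs, truncate_at = NULL)
  expect_equal(max(untrunc$weight), 1 / min(untrunc$probability),
               tolerance = 1e-12)

  # separation is refused with the offending covariate named
  sep <- data.frame(id = covs$id, flag = as.numeric(inc2))
  expect_error(estimate_ipw(inc2, sep, truncate_at = NULL), "separation")
})

test_that("unit weights reproduce the unweighted structural fit exactly", {
  tm <- true_model(n_items = c(4, 4, 4, 4), seed = 141)
  blocks <- setNames(tm$blocks, tm$item_names)
  d <- sim_items_prs(700, tm, beta_g = 0.1, seed = 142)
  spec <- build_model("bifactor", blocks)
  f0 <- fit_structural(d$items, d$prs, spec)
  w1 <- setNames(rep(1, 700), rownames(d$items))
  f1 <- weighted_structural(d$items, d$prs, spec, w1)
  expect_equal(f1$table$beta, f0$table$beta, tolerance = 1e-10)
  expect_equal(f1$table$se, f0$table$se, tolerance = 1e-10)

  # doubling all weights leaves the point estimates unchanged
  f2 <- weighted_structural(d$items, d$prs, spec, w1 * 2)
  expect_equal(f2$table$beta, f0$table$beta, tolerance = 1e-10)
})
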