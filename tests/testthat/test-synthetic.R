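# Synthetic-data generator: construction contracts, determinism, and the
# statistical structure the downstream analysis assumes.

test_that("genotypes are Hardy-Weinberg allele counts with valid metadata", {
  g <- simulate_genotypes(200, 50, c(0.05, 0.5), seed = 1)
  expect_true(all(g$dosage %in% 0:2))
  expect_equal(dim(g$dosage), c(200L, 50L))
  expect_true(all(g$snp_info$allele1 %in% c("A", "C", "G", "T")))
  expect_true(all(g$snp_info$allele1 != g$snp_info$allele2))

  # MAF fixed at 0.5: per-SNP mean dosage ~ 2 * 0.5 = 1
  g5 <- simulate_genotypes(20000, 10, c(0.5, 0.5), seed = 2)
  expect_true(all(abs(colMeans(g5$dosage) - 1) < 0.03))

  # determinism and invalid configuration
  expect_identical(simulate_genotypes(50, 20, seed = 7)$dosage,
                   simulate_genotypes(50, 20, seed = 7)$dosage)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("generating truth enforces its invariants", {
  tm <- true_model()
  expect_length(tm$item_names, 51L)
  expect_equal(as.vector(table(factor(tm$blocks,
                                      c("PE", "NEG", "DEP", "ANX")))),
               c(10L, 11L, 13L, 17L))
  expect_true(all(tm$general_loadings^2 + tm$specific_loadings^2 < 1))
  expect_true(all(vapply(tm$thresholds, function(t)
    all(diff(t) > 0) || length(t) == 1L, logical(1))))
  # threshold length must match the category count
  tm_bad <- tm
  tm_bad$thresholds[[3]] <- c(0, 1, 2)
  expect_error(validate_true_model <- bifactorPRS:::validate_true_model(tm_bad),
               "thresholds|categories")
})

test_that("factors carry the requested standardized PRS effects", {
  # null case: no dependence on the score
  prs <- with_seed_local(3, matrix(rnorm(4000), 4000, 1,
                                   dimnames = list(NULL, "SCZ")))
  eta0 <- simulate_factors(prs, beta_general(0), seed = 4)
  expect_lt(max(abs(cor(prs, eta0))), 0.05)

  # large-sample regression oracle: OLS slope of the general factor on the
  # score recovers beta
  n <- 100000
  prs_big <- with_seed_local(5, matrix(rnorm(n), n, 1,
                                       dimnames = list(NULL, "SCZ")))
  eta <- simulate_factors(prs_big, beta_general(0.06), seed = 6)
  slope <- unname(coef(lm(eta[, "GENERAL"] ~ prs_big))[2L])
  expect_lt(abs(slope - 0.06), 0.01)
  expect_lt(abs(sd(eta[, "GENERAL"]) - 1), 0.02)

  # factor columns mutually uncorrelated under the orthogonal truth
  offdiag <- cor(eta)[lower.tri(diag(5))]
  expect_lt(max(abs(offdiag)), 0.02)

  # infeasible genetic variance
  expect_error(simulate_factors(prs, beta_general(1.01), seed = 1),
               "infeasible")
})

test_that("item responses follow the threshold-crossing model", {
  tm <- true_model()
  eta <- simulate_factors(NULL, zero_betas(), n = 100000, seed = 8)
  y <- simulate_item_responses(eta, tm, seed = 9)
  expect_identical(ncol(y), 51L)
  expect_identical(unname(attr(y, "blocks")), tm$blocks)

  # all-zero-loading check via marginals: with unit-variance latent
  # responses the category frequencies equal the normal-CDF gaps between
  # thresholds (loadings do not change the marginals in this model)
  for (j in c(1L, 15L, 30L, 45L)) {
    tau <- tm$thresholds[[j]]
    probs <- diff(c(0, pnorm(tau), 1))
    emp <- tabulate(y[, j] + 1L, length(probs)) / nrow(y)
    expect_lt(max(abs(emp - probs)), 0.01)
  }

  # degenerate thresholds: everything in the top category
  tm2 <- true_model(thresholds = rep(list(c(-30, -20)), 51L),
                    n_categories = c(3, 3, 3, 3))
  y2 <- simulate_item_responses(eta[1:100, ], tm2, seed = 10)
  expect_true(all(y2 == 2L))
})

test_that("missingness is covariate-driven Bernoulli inclusion", {
  cov <- data.frame(sex = rep(0:1, 2500), background = rnorm(5000))
  m0 <- simulate_missingness(cov, c("(Intercept)" = 0, sex = 0,
                                    background = 0), n_items = 3, seed = 11)
  expect_lt(abs(mean(m0$included) - 0.5), 0.02)
  expect_true(all(m0$inclusion_probability == 0.5))
  expect_identical(m0$observed_mask[, 1L], m0$included)

  m1 <- simulate_missingness(cov, c("(Intercept)" = 0, sex = 0,
                                    background = 0), n_items = 3, seed = 11)
  expect_identical(m0$included, m1$included)
  expect_error(simulate_missingness(cov, c(unknown = 1), 3, seed = 1),
               "unknown")
})

test_that("cohort simulation wires scores, factors, items and inclusion", {
  ch <- simulate_cohort(n = 400, n_snps_per_trait = 60, seed = 21)
  expect_identical(dim(ch$true_prs), c(400L, 4L))
  expect_lt(max(abs(colMeans(ch$true_prs))), 1e-10)
  expect_true(all(abs(apply(ch$true_prs, 2, sd) - 1) < 1e-10))
  expect_identical(dim(ch$items), c(400L, 51L))
  # masked rows are all-missing; included rows keep most responses
  expect_true(all(is.na(ch$items_observed[!ch$included, ])))
  expect_gt(mean(!is.na(ch$items_observed[ch$included, ])), 0.9)
  # determinism
  ch2 <- simulate_cohort(n = 400, n_snps_per_trait = 60, seed = 21)
  expect_identical(ch$items_observed, ch2$items_observed)
  expect_identical(ch$true_prs, ch2$true_prs)
})
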