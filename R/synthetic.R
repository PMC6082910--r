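# Synthetic-data generator: genotypes, polygenic architectures, latent
# factors, ordinal item responses and covariate-driven missingness with the
# statistical structure the downstream analysis assumes, so every stage is
# testable offline.

FACTOR_NAMES <- c("GENERAL", "PE", "NEG", "DEP", "ANX")
BLOCK_NAMES <- c("PE", "NEG", "DEP", "ANX")
TRAIT_NAMES <- c("SCZ", "MDD", "NEU", "BIP")

#' Default standardized PRS effects on the bifactor-model factors
#'
#' Small standardized effects (|beta| roughly 0.01-0.09) of four psychiatric
#' polygenic risk scores (schizophrenia, major depressive disorder,
#' neuroticism, bipolar disorder) on the general psychopathology factor and
#' the four specific factors (psychotic experiences, negative dimension,
#' depression, anxiety), the magnitudes typical of adolescent-cohort
#' bifactor analyses.
#'
#' @return a 5 x 4 matrix, factors (GENERAL, PE, NEG, DEP, ANX) by PRS
#'   traits (SCZ, MDD, NEU, BIP), of standardized regression coefficients
#'   (SD of factor per SD of PRS).
#' @export
default_prs_betas <- function() {
  m <- rbind(
    GENERAL = c(0.055,  0.043,  0.071, -0.030),
    PE      = c(0.062, -0.034, -0.058, -0.023),
    NEG     = c(0.066, -0.026,  0.001,  0.033),
    DEP     = c(-0.013, -0.006, -0.024, 0.013),
    ANX     = c(0.029,  0.008,  0.052, -0.015)
  )
  colnames(m) <- TRAIT_NAMES
  m
}

#' Define a bifactor generating truth for ordinal item responses
#'
#' Describes the population model the simulator draws from: items in four
#' instrument blocks (psychotic experiences, negative dimension, depression,
#' anxiety) with standardized general and specific loadings in the delta
#' parameterization (unit latent-response variance, residual variance
#' `1 - lambda_g^2 - lambda_s^2`), per-item ascending thresholds, and
#' standardized PRS effects on each factor. Loadings and thresholds are
#' jittered deterministically from `seed` within the supplied ranges.
#'
#' @param n_items items per block (default 10/11/13/17).
#' @param n_categories observed categories per block (default 3/4/3/3; the
#'   fourth, anxiety, block is configurable because instrument response
#'   formats vary).
#' @param general_range,specific_range ranges for the general and specific
#'   standardized loadings.
#' @param prs_betas factor-by-trait matrix of standardized effects (rows
#'   GENERAL, PE, NEG, DEP, ANX), or `NULL` for no genetic effects.
#' @param thresholds optional list of per-item ascending threshold vectors
#'   (length `K - 1` each) overriding the seeded defaults.
#' @param seed integer seed controlling the jitter.
#' @return an object of class `true_model`.
#' @export
true_model <- function(n_items = c(10L, 11L, 13L, 17L),
                       n_categories = c(3L, 4L, 3L, 3L),
                       general_range = c(0.5, 0.8),
                       specific_range = c(0.3, 0.6),
                       prs_betas = default_prs_betas(),
                       thresholds = NULL,
                       seed = 1L) {
  stopifnot(length(n_items) == 4L, all(n_items >= 1L),
            length(n_categories) == 4L, all(n_categories >= 2L))
  J <- sum(n_items)
  block <- rep(BLOCK_NAMES, times = n_items)
  item_names <- unlist(lapply(seq_along(BLOCK_NAMES), function(b) {
    paste0(BLOCK_NAMES[b], seq_len(n_items[b]))
  }))
  cats <- rep(n_categories, times = n_items)

  pars <- with_seed(seed, {
    lg <- runif(J, general_range[1], general_range[2])
    ls <- runif(J, specific_range[1], specific_range[2])
    # keep residual variance strictly positive
    comm <- lg^2 + ls^2
    over <- comm > 0.95
    ls[over] <- sqrt(pmax(0.95 - lg[over]^2, 0.01))
    if (is.null(thresholds)) {
      thresholds <- lapply(seq_len(J), function(j) {
        K <- cats[j]
        # skewed symptom marginals: most respondents in the lowest category
        base <- switch(as.character(K),
                       "2" = 0.75,
                       "3" = c(0.70, 0.92),
                       "4" = c(0.55, 0.80, 0.94),
                       seq(0.5, 0.97, length.out = K - 1))
        p <- pmin(pmax(base + runif(K - 1, -0.05, 0.05), 0.02), 0.98)
        qnorm(sort(p))
      })
    }
    list(lg = lg, ls = ls, thresholds = thresholds)
  })

  if (!is.null(prs_betas)) {
    prs_betas <- as.matrix(prs_betas)
    if (nrow(prs_betas) != 5L)
      stopf("prs_betas must have 5 rows (GENERAL, PE, NEG, DEP, ANX)")
    rownames(prs_betas) <- FACTOR_NAMES
  }

  model <- structure(list(
    n_items = n_items, n_categories = cats, blocks = block,
    item_names = item_names,
    general_loadings = setNames(pars$lg, item_names),
    specific_loadings = setNames(pars$ls, item_names),
    thresholds = setNames(pars$thresholds, item_names),
    prs_betas = prs_betas, seed = seed
  ), class = "true_model")
  validate_true_model(model)
  model
}

validate_true_model <- function(m) {
  J <- length(m$item_names)
  comm <- m$general_loadings^2 + m$specific_loadings^2
  if (any(comm >= 1))
    stopf("item communality >= 1 (non-positive residual variance) for: %s",
          paste(m$item_names[comm >= 1], collapse = ", "))
  for (j in seq_len(J)) {
    tau <- m$thresholds[[j]]
    if (length(tau) != m$n_categories[j] - 1L)
      stopf("item %s: %d thresholds but %d categories (need K - 1)",
            m$item_names[j], length(tau), m$n_categories[j])
    if (any(diff(tau) <= 0))
      stopf("item %s: thresholds must be strictly ascending",
            m$item_names[j])
  }
  invisible(m)
}

#' @export
print.true_model <- function(x, ...) {
  cat("Bifactor generating truth:", length(x$item_names), "items in blocks",
      paste(sprintf("%s(%d items, %d categories)", BLOCK_NAMES, x$n_items,
                    x$n_categories[cumsum(x$n_items)]), collapse = ", "),
      "\n")
  cat(sprintf("general loadings %.2f-%.2f, specific %.2f-%.2f, seed %d\n",
              min(x$general_loadings), max(x$general_loadings),
              min(x$specific_loadings), max(x$specific_loadings), x$seed))
  invisible(x)
}

#' Simulate unlinked biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Allele counts are drawn per SNP as Binomial(2, MAF) with per-SNP minor
#' allele frequencies uniform in `maf_range`; no linkage disequilibrium or
#' population structure is simulated. Non-ambiguous allele pairs are
#' assigned so strand orientation is resolvable downstream.
#'
#' @param n respondents.
#' @param m SNPs.
#' @param maf_range interval within (0, 0.5] for per-SNP allele frequency.
#' @param seed integer seed.
#' @param snp_prefix prefix for generated SNP identifiers.
#' @return an object of class `genotype_matrix`: list with `dosage`
#'   (`n` x `m` counts of the counted allele, 0/1/2), and `snp_info`
#'   (snp_id, counted allele `allele1`, other allele `allele2`, maf).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1L,
                               snp_prefix = "rs") {
  if (!is_count(n) || !is_count(m)) stopf("n and m must be counts >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an interval within (0, 0.5]")
  with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    dosage <- vapply(seq_len(m), function(j) rbinom(n, 2L, maf[j]),
                     integer(n))
    if (n == 1L) dosage <- matrix(dosage, nrow = 1L)
    # unambiguous allele pairs only (no A/T or C/G)
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    snp_id <- sprintf("%s%05d", snp_prefix, seq_len(m))
    rownames(dosage) <- sprintf("id%05d", seq_len(n))
    colnames(dosage) <- snp_id
    structure(list(
      dosage = dosage,
      snp_info = data.frame(snp_id = snp_id,
                            allele1 = pairs[pick, 1L],
                            allele2 = pairs[pick, 2L],
                            maf = maf, stringsAsFactors = FALSE)
    ), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d respondents x %d SNPs (allele counts)\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Simulate latent psychopathology factors with standardized PRS effects
#'
#' Each factor is `sum_k beta_k * PRS_k` plus a residual whose variance is
#' chosen so the factor has unit total variance; regressing a factor on the
#' scores therefore recovers `beta` in expectation. Residuals are drawn
#' independently across factors by default (the orthogonal bifactor
#' convention); `factor_cor` imposes a residual correlation structure, e.g.
#' to generate a correlated-factors truth.
#'
#' @param prs `n` x K matrix of standardized scores (or `NULL` for no
#'   genetic effect).
#' @param betas factors-by-traits matrix of standardized effects (rows
#'   matched to factors, columns to `prs` columns); a vector is taken as a
#'   single-trait column.
#' @param n respondents (required when `prs` is `NULL`).
#' @param seed integer seed.
#' @param factor_cor residual correlation matrix across factors (default
#'   identity).
#' @return `n` x F matrix of factor scores, columns named by `betas` rows.
#' @export
simulate_factors <- function(prs = NULL, betas = default_prs_betas(),
                             n = NULL, seed = 1L, factor_cor = NULL) {
  if (is.null(betas)) betas <- matrix(0, 5L, 1L,
                                      dimnames = list(FACTOR_NAMES, NULL))
  betas <- as.matrix(betas)
  F <- nrow(betas)
  if (is.null(prs)) {
    if (is.null(n)) stopf("n is required when prs is NULL")
    prs <- matrix(0, n, ncol(betas))
  }
  prs <- as.matrix(prs)
  n <- nrow(prs)
  if (ncol(prs) != ncol(betas))
    stopf("betas has %d columns but prs has %d", ncol(betas), ncol(prs))
  S <- if (n > 1L) stats::cov(prs) else diag(ncol(prs))
  gvar <- diag(betas %*% S %*% t(betas))
  if (any(gvar >= 1))
    stopf("infeasible variance: genetic variance >= 1 for factor(s) %s",
          paste(rownames(betas)[gvar >= 1], collapse = ", "))
  if (is.null(factor_cor)) factor_cor <- diag(F)
  if (!all(dim(factor_cor) == F))
    stopf("factor_cor must be %d x %d", F, F)
  with_seed(seed, {
    resid_sd <- sqrt(1 - gvar)
    L <- chol(factor_cor)
    z <- matrix(rnorm(n * F), n, F) %*% L
    eta <- prs %*% t(betas) + z * rep(resid_sd, each = n)
    colnames(eta) <- rownames(betas)
    rownames(eta) <- rownames(prs)
    eta
  })
}

#' Simulate ordinal item responses from latent factors
#'
#' Latent response `y* = lambda_g * general + lambda_s * specific(block) +
#' e` with residual variance `1 - lambda_g^2 - lambda_s^2` (unit total
#' variance, so thresholds live on the standardized latent-response scale);
#' the observed category is the number of thresholds below `y*`.
#'
#' @param factors `n` x 5 matrix with columns GENERAL, PE, NEG, DEP, ANX
#'   (column order as in [true_model()]).
#' @param model a [true_model()].
#' @param seed integer seed for the item residuals.
#' @return integer matrix of categories in `0..K-1`, one column per item,
#'   with a `"blocks"` attribute naming each item's block.
#' @export
simulate_item_responses <- function(factors, model, seed = 1L) {
  stopifnot(inherits(model, "true_model"))
  validate_true_model(model)
  factors <- as.matrix(factors)
  if (ncol(factors) != 5L)
    stopf("factors must have 5 columns (GENERAL + 4 specifics), got %d",
          ncol(factors))
  n <- nrow(factors)
  J <- length(model$item_names)
  block_idx <- match(model$blocks, BLOCK_NAMES) + 1L  # specific factor column
  with_seed(seed, {
    y <- matrix(0L, n, J, dimnames = list(rownames(factors),
                                          model$item_names))
    for (j in seq_len(J)) {
      lg <- model$general_loadings[j]
      ls <- model$specific_loadings[j]
      rs <- sqrt(1 - lg^2 - ls^2)
      ystar <- lg * factors[, 1L] + ls * factors[, block_idx[j]] +
        rs * rnorm(n)
      y[, j] <- findInterval(ystar, model$thresholds[[j]])
    }
    attr(y, "blocks") <- setNames(model$blocks, model$item_names)
    y
  })
}

#' Simulate covariate-dependent inclusion (missingness) for a cohort
#'
#' Inclusion is missing-at-random given observed auxiliary covariates: the
#' inclusion probability is `plogis(X %*% coefficients)` and the indicator
#' is Bernoulli. The mask hides all item responses of non-included
#' respondents. Missingness never depends on the latent factors directly,
#' so inverse-probability weighting on the covariates is a consistent
#' correction by construction.
#'
#' @param covariates data.frame/matrix of auxiliary covariates (columns
#'   referenced by `coefficients` names; an intercept is added).
#' @param coefficients named numeric vector of logistic coefficients;
#'   `"(Intercept)"` entry optional (default 0).
#' @param n_items number of item columns to mask.
#' @param seed integer seed.
#' @return list with `inclusion_probability`, logical `included`, and
#'   logical `observed_mask` (`n` x `n_items`, `TRUE` where observed).
#' @export
simulate_missingness <- function(covariates, coefficients, n_items,
                                 seed = 1L) {
  covariates <- as.data.frame(covariates)
  icpt <- if ("(Intercept)" %in% names(coefficients))
    coefficients[["(Intercept)"]] else 0
  slopes <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  miss <- setdiff(names(slopes), names(covariates))
  if (length(miss) > 0)
    stopf("coefficients reference unknown covariates: %s",
          paste(miss, collapse = ", "))
  lp <- rep(icpt, nrow(covariates))
  for (v in names(slopes)) lp <- lp + slopes[[v]] * covariates[[v]]
  with_seed(seed, {
    p <- plogis(lp)
    inc <- runif(length(p)) < p
    mask <- matrix(rep(inc, n_items), ncol = n_items)
    list(inclusion_probability = p, included = inc, observed_mask = mask)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Wires the generator end to end: unlinked genotypes split into one SNP
#' panel per discovery trait, simulated discovery summary statistics
#' (weights and P-values) for each panel, standardized polygenic scores at
#' `p_threshold`, latent factors with the model's PRS effects, ordinal item
#' responses, auxiliary covariates (sex; a family-background score
#' negatively correlated with the general factor), and covariate-driven
#' inclusion. The default missingness coefficients make the analysis sample
#' skew female and more advantaged, with roughly three quarters included.
#'
#' @param n respondents.
#' @param model a [true_model()]; its `prs_betas` columns define the traits.
#' @param n_snps_per_trait SNPs per discovery panel.
#' @param maf_range allele-frequency interval for [simulate_genotypes()].
#' @param p_threshold discovery P-value threshold used to build the true
#'   scores (default 0.05, the primary-analysis threshold).
#' @param missingness_coefficients logistic coefficients on `sex` and
#'   `background` (plus `"(Intercept)"`) for inclusion.
#' @param item_missing_rate sporadic item-level missingness among included
#'   respondents.
#' @param factor_cor optional residual factor correlation (see
#'   [simulate_factors()]).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return an object of class `synthetic_cohort` (see Details in the
#'   package vignette).
#' @export
simulate_cohort <- function(n = 3000L, model = true_model(),
                            n_snps_per_trait = 150L,
                            maf_range = c(0.05, 0.5),
                            p_threshold = 0.05,
                            missingness_coefficients = c(
                              "(Intercept)" = 0.6, sex = 0.4,
                              background = 0.5),
                            item_missing_rate = 0.02,
                            factor_cor = NULL,
                            seed = 1L) {
  stopifnot(inherits(model, "true_model"))
  traits <- colnames(model$prs_betas)
  if (is.null(traits)) traits <- paste0("TRAIT", seq_len(ncol(model$prs_betas)))
  K <- length(traits)
  m_total <- K * n_snps_per_trait
  geno <- simulate_genotypes(n, m_total, maf_range, seed = seed + 1L)
  panel <- rep(traits, each = n_snps_per_trait)

  sumstats <- with_seed(seed + 2L, {
    lapply(setNames(traits, traits), function(tr) {
      idx <- which(panel == tr)
      m <- length(idx)
      assoc <- runif(m) < 0.3
      p <- ifelse(assoc, rbeta(m, 0.2, 4), runif(m))
      p <- pmin(pmax(p, 1e-12), 1)
      info <- geno$snp_info[idx, ]
      flip <- runif(m) < 0.5  # effect allele is sometimes the other allele
      data.frame(
        snp_id = info$snp_id,
        effect_allele = ifelse(flip, info$allele2, info$allele1),
        other_allele = ifelse(flip, info$allele1, info$allele2),
        weight = rnorm(m, 0, 0.08),
        p_value = p,
        stringsAsFactors = FALSE
      )
    })
  })

  # true standardized scores: counted-allele dosage weighted by the
  # harmonized discovery weights for SNPs passing the threshold
  prs <- sapply(traits, function(tr) {
    ss <- sumstats[[tr]]
    keep <- ss$p_value <= p_threshold
    ss <- ss[keep, , drop = FALSE]
    info <- geno$snp_info[match(ss$snp_id, geno$snp_info$snp_id), ]
    sgn <- ifelse(ss$effect_allele == info$allele1, 1, -1)
    g <- geno$dosage[, ss$snp_id, drop = FALSE]
    raw <- as.vector(g %*% (ss$weight * sgn)) +
      2 * sum(ss$weight[sgn < 0])  # (2 - g) contribution of flipped SNPs
    as.vector(scale(raw))
  })
  rownames(prs) <- rownames(geno$dosage)

  factors <- simulate_factors(prs, model$prs_betas, seed = seed + 3L,
                              factor_cor = factor_cor)
  items <- simulate_item_responses(factors, model, seed = seed + 4L)

  covariates <- with_seed(seed + 5L, {
    data.frame(
      id = rownames(geno$dosage),
      sex = rbinom(n, 1L, 0.5),
      background = -0.4 * factors[, "GENERAL"] + sqrt(1 - 0.16) * rnorm(n),
      stringsAsFactors = FALSE
    )
  })

  miss <- simulate_missingness(covariates[, c("sex", "background")],
                               missingness_coefficients,
                               n_items = ncol(items), seed = seed + 6L)
  observed <- miss$observed_mask
  if (item_missing_rate > 0) {
    observed <- observed & with_seed(seed + 7L, {
      matrix(runif(length(items)) >= item_missing_rate, nrow(items))
    })
  }
  items_observed <- items
  items_observed[!observed] <- NA_integer_
  attr(items_observed, "blocks") <- attr(items, "blocks")

  structure(list(
    genotypes = geno, sumstats = sumstats, true_prs = prs,
    factor_scores = factors, items = items,
    items_observed = items_observed, covariates = covariates,
    inclusion_probability = miss$inclusion_probability,
    included = miss$included, observed_mask = observed,
    model = model, p_threshold = p_threshold, seed = seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d respondents, %d SNPs, %d items, ",
                     "%d traits; %d (%.0f%%) included\n"),
              nrow(x$items), ncol(x$genotypes$dosage), ncol(x$items),
              ncol(x$true_prs), sum(x$included),
              100 * mean(x$included)))
  invisible(x)
}
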