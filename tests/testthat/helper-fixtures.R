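# Shared fixtures, built in code at test time.

FN <- c("GENERAL", "PE", "NEG", "DEP", "ANX")

beta_general <- function(b) {
  matrix(c(b, 0, 0, 0, 0), 5L, 1L, dimnames = list(FN, "SCZ"))
}

zero_betas <- function() matrix(0, 5L, 1L, dimnames = list(FN, NULL))

# population loading matrix (items x 5) implied by a true_model
truth_lambda <- function(tm) {
  L <- cbind(tm$general_loadings,
             sapply(c("PE", "NEG", "DEP", "ANX"), function(b)
               ifelse(tm$blocks == b, tm$specific_loadings, 0)))
  colnames(L) <- FN
  rownames(L) <- tm$item_names
  L
}

# population polychoric matrix of a bifactor truth
truth_corr <- function(tm) {
  L <- truth_lambda(tm)
  R <- tcrossprod(L)
  diag(R) <- 1
  R
}

# wrap a population correlation matrix + thresholds as a polychoric summary
# (constant nominal precision, no influence); for population-recovery tests
population_poly <- function(R, thresholds, n = 1e6) {
  J <- ncol(R)
  structure(list(R = R, avar = rep(1e-4, J * (J - 1) / 2),
                 n_pairwise = rep(n, J * (J - 1) / 2),
                 thresholds = thresholds, influence = NULL,
                 n = n, wtot = n, weights = rep(1, 1),
                 item_names = colnames(R)),
            class = "polychoric_summary")
}

# view a true_model as a fitted measurement object (population parameters),
# usable for scoring and the marginal likelihood
truth_as_fit <- function(tm) {
  L <- truth_lambda(tm)
  spec <- build_model("bifactor", setNames(tm$blocks, tm$item_names))
  comm <- tm$general_loadings^2 + tm$specific_loadings^2
  list(structure = "bifactor", spec = spec, loadings = L,
       phi = diag(5L), thresholds = tm$thresholds,
       residual_variance = 1 - comm, converged = TRUE,
       n_parameters = 2L * length(comm) + sum(lengths(tm$thresholds)))
}

# simulate an item matrix (ids in rownames) plus a standardized exposure
# with a given effect on the general factor
sim_items_prs <- function(n, tm, beta_g = 0, seed = 1L) {
  prs <- with_seed_local(seed, matrix(rnorm(n), n, 1,
                                      dimnames = list(sprintf("id%05d",
                                                              seq_len(n)),
                                                      "SCZ")))
  eta <- simulate_factors(prs, beta_general(beta_g), seed = seed + 1L)
  y <- simulate_item_responses(eta, tm, seed = seed + 2L)
  rownames(y) <- rownames(prs)
  list(items = y, prs = setNames(prs[, 1L], rownames(prs)), factors = eta)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# assemble a bifactor fit object from raw loadings (reliability tests)
make_bifactor_fit <- function(lg, ls, blocks) {
  bn <- unique(blocks)
  L <- cbind(lg, sapply(bn, function(b) ifelse(blocks == b, ls, 0)))
  colnames(L) <- c("GENERAL", bn)
  spec <- build_model("bifactor", setNames(blocks, paste0("it",
                                                          seq_along(lg))))
  list(structure = "bifactor", spec = spec, loadings = L,
       phi = diag(ncol(L)))
}

# small summary-statistics data.frame writer for PRS tests
toy_sumstats <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "G", "T"),
    other_allele = c("G", "A", "C"),
    weight = c(0.1, -0.2, 0.3),
    p_value = c(0.01, 0.2, 1e-9),
    stringsAsFactors = FALSE
  )
}
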