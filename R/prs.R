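# Polygenic risk scoring from discovery GWAS summary statistics:
# P-value thresholding, allele harmonization against the counted allele of
# the target genotypes, weighted allele-count summation and
# standardization.

VALID_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Read discovery GWAS summary statistics
#'
#' Reads a delimited text file with one record per SNP carrying the SNP
#' identifier, effect and other allele, effect size on the discovery scale
#' (log-odds or beta) and association P-value. Column names are mapped via
#' `col_map`; the delimiter is sniffed (tab or comma). Records with
#' non-ACGT alleles are dropped with a message; duplicated identifiers and
#' P-values outside (0, 1] are errors.
#'
#' @param path file path.
#' @param col_map named character vector mapping the five canonical fields
#'   (`snp_id`, `effect_allele`, `other_allele`, `weight`, `p_value`) to the
#'   file's column names.
#' @return a `data.frame` of class `gwas_sumstats` with the five canonical
#'   columns.
#' @export
read_summary_stats <- function(path,
                               col_map = c(snp_id = "snp_id",
                                           effect_allele = "effect_allele",
                                           other_allele = "other_allele",
                                           weight = "weight",
                                           p_value = "p_value")) {
  if (!file.exists(path)) stopf("summary statistics file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "weight", "p_value")
  missing_map <- setdiff(need, names(col_map))
  if (length(missing_map) > 0)
    stopf("col_map lacks entries for: %s", paste(missing_map, collapse = ", "))
  absent <- setdiff(unname(col_map[need]), names(df))
  if (length(absent) > 0)
    stopf("summary statistics file lacks column(s): %s",
          paste(absent, collapse = ", "))
  out <- data.frame(
    snp_id = as.character(df[[col_map[["snp_id"]]]]),
    effect_allele = toupper(as.character(df[[col_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(df[[col_map[["other_allele"]]]])),
    weight = as.numeric(df[[col_map[["weight"]]]]),
    p_value = as.numeric(df[[col_map[["p_value"]]]]),
    stringsAsFactors = FALSE
  )
  bad_allele <- !(out$effect_allele %in% VALID_BASES) |
    !(out$other_allele %in% VALID_BASES)
  if (any(bad_allele)) {
    message(sprintf("dropping %d record(s) with non-ACGT alleles: %s",
                    sum(bad_allele),
                    paste(head(out$snp_id[bad_allele], 5L), collapse = ", ")))
    out <- out[!bad_allele, , drop = FALSE]
  }
  dup <- duplicated(out$snp_id)
  if (any(dup))
    stopf("duplicated SNP identifier(s): %s",
          paste(unique(out$snp_id[dup]), collapse = ", "))
  bad_p <- !is.finite(out$p_value) | out$p_value <= 0 | out$p_value > 1
  if (any(bad_p))
    stopf("p_value outside (0, 1] for: %s",
          paste(head(out$snp_id[bad_p], 5L), collapse = ", "))
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Select SNPs at a discovery P-value threshold
#'
#' @param stats summary statistics (from [read_summary_stats()] or a
#'   data.frame with the canonical columns).
#' @param p_threshold threshold in (0, 1]; SNPs with `p_value <=
#'   p_threshold` are kept. The genome-wide level is conventionally 5e-8
#'   but is overridable (some discovery studies use 1e-8).
#' @return the subset, with attribute `n_selected`.
#' @export
select_snps <- function(stats, p_threshold) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1)
    stopf("p_threshold must be a single value in (0, 1]")
  keep <- stats$p_value <= p_threshold
  if (!any(keep))
    warnf("no SNPs pass P-value threshold %g", p_threshold)
  out <- stats[keep, , drop = FALSE]
  attr(out, "n_selected") <- sum(keep)
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Harmonize discovery weights to the counted allele of the genotypes
#'
#' For each SNP shared between the summary statistics and the genotype
#' panel: if the effect allele equals the counted allele the weight applies
#' to the dosage directly; if it equals the other allele the contribution is
#' counted on `2 - g`; strand flips are resolved by complementing both
#' alleles; strand-ambiguous A/T and C/G SNPs are dropped when
#' `drop_ambiguous` (the default) because orientation cannot be resolved
#' without allele-frequency matching; irreconcilable allele pairs are
#' dropped and logged.
#'
#' @param stats summary statistics.
#' @param genotypes a `genotype_matrix` (dosages count `allele1`).
#' @param drop_ambiguous drop A/T and C/G SNPs.
#' @return object of class `harmonized_weights`: data.frame (`snp_id`,
#'   `weight`, `flip`) of usable SNPs plus a `log` attribute: data.frame of
#'   per-SNP orientation decisions (`used`, `flipped`, `strand_flipped`,
#'   `ambiguous`, `irreconcilable`, `absent`).
#' @export
harmonize_alleles <- function(stats, genotypes, drop_ambiguous = TRUE) {
  info <- genotypes$snp_info
  shared <- intersect(stats$snp_id, info$snp_id)
  if (length(shared) == 0L)
    stopf("no SNPs shared between summary statistics and genotypes")
  st <- stats[match(shared, stats$snp_id), , drop = FALSE]
  gi <- info[match(shared, info$snp_id), , drop = FALSE]

  ea <- st$effect_allele; oa <- st$other_allele
  a1 <- gi$allele1; a2 <- gi$allele2
  ambiguous <- ea == COMPLEMENT[oa]
  direct <- ea == a1 & oa == a2
  flipped <- ea == a2 & oa == a1
  strand_direct <- COMPLEMENT[ea] == a1 & COMPLEMENT[oa] == a2
  strand_flipped <- COMPLEMENT[ea] == a2 & COMPLEMENT[oa] == a1

  status <- rep("irreconcilable", length(shared))
  flip <- rep(NA, length(shared))
  status[strand_flipped] <- "strand_flipped"; flip[strand_flipped] <- TRUE
  status[strand_direct] <- "strand"; flip[strand_direct] <- FALSE
  status[flipped] <- "flipped"; flip[flipped] <- TRUE
  status[direct] <- "direct"; flip[direct] <- FALSE
  if (drop_ambiguous) {
    status[ambiguous] <- "ambiguous"
    flip[ambiguous] <- NA
  }
  usable <- !is.na(flip)
  log <- data.frame(snp_id = shared, status = status, used = usable,
                    stringsAsFactors = FALSE)
  absent <- setdiff(stats$snp_id, shared)
  if (length(absent) > 0)
    log <- rbind(log, data.frame(snp_id = absent, status = "absent",
                                 used = FALSE, stringsAsFactors = FALSE))
  out <- data.frame(snp_id = shared[usable],
                    weight = st$weight[usable],
                    flip = flip[usable], stringsAsFactors = FALSE)
  attr(out, "log") <- log
  class(out) <- c("harmonized_weights", "data.frame")
  out
}

#' Compute polygenic risk scores
#'
#' Raw score per respondent: `sum_j g*_ij w_j` where `g*` is the harmonized
#' dosage of the effect allele (`g` or `2 - g` for orientation-flipped
#' SNPs). Missing dosages are mean-imputed as twice the sample frequency of
#' the counted allele before orientation. Standardization refuses
#' zero-variance scores.
#'
#' @param genotypes a `genotype_matrix`.
#' @param harmonized a `harmonized_weights` (from [harmonize_alleles()]).
#' @param standardize also return z-scores (mean 0, SD 1).
#' @param p_threshold optional threshold recorded in the output.
#' @return object of class `polygenic_score`: data.frame (`id`, `raw`,
#'   and `z` when standardized) with attributes `n_snps`, `p_threshold`.
#' @export
compute_prs <- function(genotypes, harmonized, standardize = TRUE,
                        p_threshold = NA_real_) {
  if (nrow(harmonized) == 0L)
    stopf("no SNPs survive harmonization; cannot score")
  g <- genotypes$dosage[, harmonized$snp_id, drop = FALSE]
  g <- apply(g, 2L, function(col) {
    miss <- is.na(col)
    # mean dosage equals 2 x counted-allele frequency
    if (any(miss)) col[miss] <- mean(col[!miss])
    col
  })
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(genotypes$dosage))
  w <- harmonized$weight
  flip <- harmonized$flip
  # orientation flip: contribution (2 - g) * w  ==  g * (-w) + 2w
  raw <- as.vector(g %*% ifelse(flip, -w, w)) + 2 * sum(w[flip])
  out <- data.frame(id = rownames(genotypes$dosage), raw = raw,
                    stringsAsFactors = FALSE)
  if (standardize) {
    s <- sd(raw)
    if (!is.finite(s) || s < 1e-12)
      stopf("cannot standardize: score variance is zero")
    out$z <- (raw - mean(raw)) / s
  }
  attr(out, "n_snps") <- nrow(harmonized)
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("polygenic_score", "data.frame")
  out
}

#' Score a trait at one or more discovery P-value thresholds
#'
#' Convenience wrapper: threshold selection, allele harmonization and
#' scoring in one call.
#'
#' @param stats summary statistics.
#' @param genotypes a `genotype_matrix`.
#' @param p_thresholds thresholds (defaults 0.5, 0.05, 1e-5, 5e-8).
#' @param drop_ambiguous see [harmonize_alleles()].
#' @param standardize see [compute_prs()].
#' @return named list of `polygenic_score` objects, one per threshold.
#' @export
score_prs <- function(stats, genotypes,
                      p_thresholds = c(0.5, 0.05, 1e-5, 5e-8),
                      drop_ambiguous = TRUE, standardize = TRUE) {
  out <- lapply(p_thresholds, function(pt) {
    sel <- select_snps(stats, pt)
    if (nrow(sel) == 0L) return(NULL)
    harm <- harmonize_alleles(sel, genotypes, drop_ambiguous)
    compute_prs(genotypes, harm, standardize, p_threshold = pt)
  })
  names(out) <- sprintf("PT_%g", p_thresholds)
  out
}

#' Pearson correlations among polygenic scores
#'
#' @param scores named list of `polygenic_score` objects (>= 2) on
#'   overlapping respondents.
#' @param use which score column to correlate (`"z"` or `"raw"`).
#' @return correlation matrix over the respondent intersection, with
#'   attribute `n` (respondents used).
#' @export
prs_correlation_report <- function(scores, use = c("z", "raw")) {
  use <- match.arg(use)
  if (length(scores) < 2L) stopf("need at least two score sets")
  ids <- Reduce(intersect, lapply(scores, function(s) s$id))
  if (length(ids) < 2L)
    stopf("fewer than two overlapping respondents across score sets")
  m <- sapply(scores, function(s) s[[use]][match(ids, s$id)])
  r <- cor(m)
  attr(r, "n") <- length(ids)
  r
}
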