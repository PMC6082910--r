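# Polygenic scoring: file contracts, thresholding, allele harmonization,
# and the scoring algebra.

write_toy <- function(df, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("summary statistics reader validates its contract", {
  ss <- read_summary_stats(write_toy(toy_sumstats()))
  expect_s3_class(ss, "gwas_sumstats")
  expect_identical(nrow(ss), 3L)

  # comma-delimited with a custom column map
  df <- toy_sumstats()
  names(df) <- c("SNP", "A1", "A2", "BETA", "P")
  p2 <- write_toy(df, sep = ",")
  ss2 <- read_summary_stats(p2, col_map = c(snp_id = "SNP",
                                            effect_allele = "A1",
                                            other_allele = "A2",
                                            weight = "BETA", p_value = "P"))
  expect_equal(ss2$weight, ss$weight)

  dup <- rbind(toy_sumstats(), toy_sumstats()[1L, ])
  expect_error(read_summary_stats(write_toy(dup)), "rs1")

  bad <- toy_sumstats(); bad$p_value[2] <- 0
  expect_error(read_summary_stats(write_toy(bad)), "p_value")

  dropme <- toy_sumstats(); dropme$effect_allele[1] <- "N"
  expect_message(out <- read_summary_stats(write_toy(dropme)), "non-ACGT")
  expect_identical(nrow(out), 2L)

  nocol <- toy_sumstats()[, -5L]
  expect_error(read_summary_stats(write_toy(nocol)), "p_value")
})

test_that("threshold selection keeps SNPs at or below P_T", {
  ss <- toy_sumstats()  # p = 0.01, 0.2, 1e-9
  expect_identical(nrow(select_snps(ss, 0.05)), 1L + 1L)  # 0.01 and 1e-9
  expect_identical(nrow(select_snps(ss, 1.0)), 3L)
  expect_identical(nrow(select_snps(ss, 5e-8)), 1L)
  # stricter genome-wide rule, as used by some discovery studies
  expect_identical(nrow(select_snps(ss, 1e-8)), 0L + 1L)
  expect_warning(select_snps(ss, 1e-15), "no SNPs")
  expect_error(select_snps(ss, 0), "threshold")
})

test_that("allele harmonization resolves orientation and drops ambiguity", {
  geno <- list(dosage = matrix(c(0L, 1L, 2L), 3, 4,
                               dimnames = list(paste0("id", 1:3),
                                               paste0("rs", 1:4))),
               snp_info = data.frame(
                 snp_id = paste0("rs", 1:4),
                 allele1 = c("A", "G", "C", "A"),
                 allele2 = c("G", "A", "T", "T"),
                 maf = rep(0.3, 4), stringsAsFactors = FALSE))
  class(geno) <- "genotype_matrix"
  ss <- data.frame(snp_id = paste0("rs", 1:4),
                   effect_allele = c("A", "A", "G", "A"),
                   other_allele = c("G", "G", "A", "T"),
                   weight = c(0.5, 0.5, 0.5, 0.5),
                   p_value = rep(0.01, 4), stringsAsFactors = FALSE)
  h <- harmonize_alleles(ss, geno)
  log <- attr(h, "log")
  expect_identical(log$status[log$snp_id == "rs1"], "direct")
  expect_identical(log$status[log$snp_id == "rs2"], "flipped")
  # rs3: G/A vs genotype C/T resolves by strand complement (G->C, A->T)
  expect_identical(log$status[log$snp_id == "rs3"], "strand")
  expect_identical(log$status[log$snp_id == "rs4"], "ambiguous")
  expect_identical(sort(h$snp_id), c("rs1", "rs2", "rs3"))
  expect_identical(h$flip[h$snp_id == "rs1"], FALSE)
  expect_identical(h$flip[h$snp_id == "rs2"], TRUE)

  h2 <- harmonize_alleles(ss, geno, drop_ambiguous = FALSE)
  expect_true("rs4" %in% h2$snp_id)
})

test_that("scoring matches hand sums and a brute-force oracle", {
  # hand example: g = (0,1,2), w = (0.1, -0.2, 0.3) on one respondent
  geno <- list(dosage = matrix(c(0L, 1L, 2L), 1, 3,
                               dimnames = list("id1", paste0("rs", 1:3))),
               snp_info = data.frame(snp_id = paste0("rs", 1:3),
                                     allele1 = c("A", "A", "A"),
                                     allele2 = c("G", "G", "G"),
                                     maf = 0.3, stringsAsFactors = FALSE))
  class(geno) <- "genotype_matrix"
  h <- data.frame(snp_id = paste0("rs", 1:3), weight = c(0.1, -0.2, 0.3),
                  flip = FALSE, stringsAsFactors = FALSE)
  class(h) <- c("harmonized_weights", "data.frame")
  ps <- compute_prs(geno, h, standardize = FALSE)
  expect_equal(ps$raw, 0 * 0.1 + 1 * -0.2 + 2 * 0.3)

  # zero weights: degenerate standardization refused
  h0 <- h; h0$weight <- 0
  expect_equal(compute_prs(geno, h0, standardize = FALSE)$raw, 0)
  expect_error(compute_prs(geno, h0, standardize = TRUE), "variance")

  # brute-force double loop equals the vectorized path exactly,
  # including orientation flips
  g <- simulate_genotypes(100, 200, seed = 31)
  set.seed(32)
  hw <- data.frame(snp_id = g$snp_info$snp_id,
                   weight = rnorm(200, 0, 0.1),
                   flip = runif(200) < 0.4, stringsAsFactors = FALSE)
  class(hw) <- c("harmonized_weights", "data.frame")
  fast <- compute_prs(g, hw, standardize = TRUE)
  slow <- numeric(100)
  for (i in 1:100) {
    acc <- 0
    for (j in 1:200) {
      gij <- g$dosage[i, j]
      acc <- acc + (if (hw$flip[j]) 2 - gij else gij) * hw$weight[j]
    }
    slow[i] <- acc
  }
  expect_equal(fast$raw, slow, tolerance = 1e-12)
  expect_lt(abs(mean(fast$z)), 1e-10)
  expect_lt(abs(sd(fast$z) - 1), 1e-10)
})

test_that("scoring is invariant to allele-orientation recoding and linear", {
  g <- simulate_genotypes(60, 40, seed = 41)
  w <- with_seed_local(42, rnorm(40, 0, 0.1))
  h1 <- data.frame(snp_id = g$snp_info$snp_id, weight = w, flip = FALSE,
                   stringsAsFactors = FALSE)
  class(h1) <- c("harmonized_weights", "data.frame")
  # recode SNP 5: count the other allele (dosage 2 - g) and flag the flip
  g2 <- g
  g2$dosage[, 5] <- 2L - g2$dosage[, 5]
  tmp <- g2$snp_info$allele1[5]
  g2$snp_info$allele1[5] <- g2$snp_info$allele2[5]
  g2$snp_info$allele2[5] <- tmp
  h2 <- h1; h2$flip[5] <- TRUE
  expect_equal(compute_prs(g, h1, FALSE)$raw, compute_prs(g2, h2, FALSE)$raw,
               tolerance = 1e-12)

  # linearity: PRS(w1 + w2) = PRS(w1) + PRS(w2)
  w2 <- with_seed_local(43, rnorm(40, 0, 0.1))
  hsum <- h1; hsum$weight <- w + w2
  hb <- h1; hb$weight <- w2
  expect_equal(compute_prs(g, hsum, FALSE)$raw,
               compute_prs(g, h1, FALSE)$raw + compute_prs(g, hb, FALSE)$raw,
               tolerance = 1e-12)
})

test_that("score correlations behave at the identity and sign boundaries", {
  g <- simulate_genotypes(300, 50, seed = 51)
  w <- with_seed_local(52, rnorm(50, 0, 0.1))
  mk <- function(wv) {
    h <- data.frame(snp_id = g$snp_info$snp_id, weight = wv, flip = FALSE,
                    stringsAsFactors = FALSE)
    class(h) <- c("harmonized_weights", "data.frame")
    compute_prs(g, h)
  }
  s1 <- mk(w); s2 <- mk(-w)
  r <- prs_correlation_report(list(a = s1, self = s1, neg = s2))
  expect_equal(unname(r["a", "self"]), 1)
  expect_equal(unname(r["a", "neg"]), -1)

  # independent weight vectors on disjoint SNP sets: near-zero correlation
  wA <- w; wA[26:50] <- 0
  wB <- numeric(50); wB[26:50] <- with_seed_local(53, rnorm(25, 0, 0.1))
  r2 <- prs_correlation_report(list(A = mk(wA), B = mk(wB)))
  expect_lt(abs(r2["A", "B"]), 0.15)
  expect_error(prs_correlation_report(list(only = s1)), "two")
})
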