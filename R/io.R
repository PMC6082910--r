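# File interchange: ordinal item tables (CSV), block maps (YAML),
# genotypes (dosage TSV or VCF), summary statistics and truth parameters.

#' Read an ordinal item-response table
#'
#' CSV with a respondent-id column and one integer column per item.
#' Category labels are remapped per item to contiguous `0..K-1` codes
#' (declared dialects `"zero"` / `"one"` shift by a constant instead, so
#' unobserved intermediate categories are preserved); blank cells are
#' missing; values outside the declared range become missing with a
#' warning.
#'
#' @param path CSV path.
#' @param blocks named character vector (item -> block), e.g. from
#'   [read_blocks()]; its order defines the item order.
#' @param id_col name of the respondent-id column.
#' @param dialect `"observed"` (remap observed sorted labels to `0..K-1`),
#'   `"zero"` (already 0-based) or `"one"` (1-based).
#' @return integer matrix with respondent rownames and a `"blocks"`
#'   attribute.
#' @export
read_items <- function(path, blocks, id_col = "id",
                       dialect = c("observed", "zero", "one")) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(df))
    stopf("items file lacks id column '%s'", id_col)
  unknown <- setdiff(names(blocks), names(df))
  if (length(unknown) > 0)
    stopf("block map names item(s) absent from the file: %s",
          paste(unknown, collapse = ", "))
  m <- as.matrix(df[, names(blocks), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[id_col]])
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    bad <- !is.na(v) & (v != floor(v))
    if (any(bad)) {
      warnf("item %s: %d non-integer value(s) set to missing",
            colnames(m)[j], sum(bad))
      v[bad] <- NA
    }
    v <- switch(dialect,
                observed = match(v, sort(unique(v[!is.na(v)]))) - 1L,
                zero = as.integer(v),
                one = as.integer(v) - 1L)
    neg <- !is.na(v) & v < 0L
    if (any(neg)) {
      warnf("item %s: %d value(s) below the category range set to missing",
            colnames(m)[j], sum(neg))
      v[neg] <- NA_integer_
    }
    out[, j] <- v
  }
  attr(out, "blocks") <- blocks
  out
}

#' Read an item-block map from YAML
#'
#' Layout: `block_name: [item1, item2, ...]` per block.
#'
#' @param path YAML path.
#' @return named character vector item -> block, in file order.
#' @export
read_blocks <- function(path) {
  y <- yaml::read_yaml(path)
  items <- unlist(y, use.names = FALSE)
  setNames(rep(names(y), lengths(y)), items)
}

#' Write an item table as CSV
#'
#' Respondent id first, then integer categories; missing cells are empty.
#' @param items item matrix (rownames are ids).
#' @param path output path.
#' @export
write_items_csv <- function(items, path) {
  df <- data.frame(id = rownames(items), as.data.frame(items),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a block map as YAML
#' @param blocks named character vector item -> block.
#' @param path output path.
#' @export
write_blocks_yaml <- function(blocks, path) {
  y <- split(names(blocks), factor(blocks, levels = unique(blocks)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write summary statistics as tab-delimited text
#' @param stats canonical five-column summary statistics.
#' @param path output path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a dosage TSV
#'
#' Header: `id`, then one column per SNP named `snp|counted|other` so the
#' allele orientation travels with the dosages.
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  info <- genotypes$snp_info
  cn <- paste(info$snp_id, info$allele1, info$allele2, sep = "|")
  df <- data.frame(id = rownames(genotypes$dosage), genotypes$dosage,
                   check.names = FALSE)
  names(df) <- c("id", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field)
#' @param genotypes a `genotype_matrix` (dosages count the ALT allele).
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  d <- genotypes$dosage
  info <- genotypes$snp_info
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    writeLines(paste(c("1", j, info$snp_id[j], info$allele2[j],
                       info$allele1[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a dosage TSV or a VCF
#'
#' Dosage TSV as written by [write_dosage_tsv()] (SNP columns
#' `snp|counted|other`); VCF via the `vcfR` package, counting ALT alleles
#' from the GT field.
#'
#' @param path file path.
#' @param format `"dosage"` or `"vcf"` (guessed from the extension by
#'   default).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "dosage") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    parts <- strsplit(colnames(m), "|", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stopf("dosage header must use 'snp|counted|other' column names")
    info <- data.frame(snp_id = vapply(parts, `[`, "", 1L),
                       allele1 = vapply(parts, `[`, "", 2L),
                       allele2 = vapply(parts, `[`, "", 3L),
                       maf = colMeans(m, na.rm = TRUE) / 2,
                       stringsAsFactors = FALSE)
    rownames(m) <- ids
    colnames(m) <- info$snp_id
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stopf("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), integer(1)))
    }
    m <- apply(gt, 1L, count_alt)  # respondents x SNPs
    if (is.null(dim(m)))
      m <- matrix(m, ncol = nrow(gt), dimnames = list(colnames(gt), NULL))
    fix <- vcfR::getFIX(v)
    info <- data.frame(snp_id = unname(fix[, "ID"]),
                       allele1 = unname(fix[, "ALT"]),
                       allele2 = unname(fix[, "REF"]),
                       maf = colMeans(m, na.rm = TRUE) / 2,
                       stringsAsFactors = FALSE)
    colnames(m) <- info$snp_id
    rownames(m) <- colnames(gt)
    storage.mode(m) <- "integer"
  }
  structure(list(dosage = m, snp_info = info), class = "genotype_matrix")
}

#' Write generating-truth parameters as YAML (for recovery tests)
#' @param model a [true_model()].
#' @param path output path.
#' @export
write_truth_yaml <- function(model, path) {
  yaml::write_yaml(list(
    n_items = as.integer(model$n_items),
    blocks = as.list(setNames(model$blocks, model$item_names)),
    n_categories = as.integer(model$n_categories),
    general_loadings = as.numeric(model$general_loadings),
    specific_loadings = as.numeric(model$specific_loadings),
    thresholds = lapply(model$thresholds, as.numeric),
    prs_betas = if (!is.null(model$prs_betas))
      apply(model$prs_betas, 2L, as.numeric, simplify = FALSE) else NULL,
    seed = as.integer(model$seed)
  ), path, precision = 12L)
  invisible(path)
}
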