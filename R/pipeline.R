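# End-to-end orchestration: scoring -> inclusion filter -> measurement
# model comparison -> reliability -> association (+ permutation and
# inverse-probability weighting), with seeded, provenance-stamped outputs.

#' Assemble a pipeline configuration
#'
#' Validates paths and collects every tuning knob and seed in one place so
#' a run is fully reproducible. `sumstats` is a named list (one file per
#' discovery trait); `covariates` is optional and enables the IPW
#' sensitivity analysis.
#'
#' @param sumstats named list of summary-statistics paths.
#' @param genotypes genotype file path (dosage TSV or VCF).
#' @param items item CSV path.
#' @param blocks block-map YAML path.
#' @param covariates optional covariate CSV path (id column + auxiliary
#'   variables; must cover scored respondents).
#' @param out_dir output directory (created).
#' @param p_thresholds scoring thresholds; the first is the primary one
#'   used downstream.
#' @param structures structures to fit for associations.
#' @param min_per_block inclusion rule for association analyses.
#' @param n_perm permutations for the adjusted p-values.
#' @param n_points integration points for the information criteria.
#' @param seed master seed (stage seeds are derived from it).
#' @param compute_ic fit the marginal-likelihood information criteria
#'   (the slowest stage).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sumstats, genotypes, items, blocks,
                            covariates = NULL, out_dir = "results",
                            p_thresholds = c(0.05, 0.5, 1e-5, 5e-8),
                            structures = c("correlated", "bifactor"),
                            min_per_block = 4L, n_perm = 1000L,
                            n_points = 8000L, seed = 1L,
                            compute_ic = TRUE) {
  paths <- c(unlist(sumstats), genotypes = genotypes, items = items,
             blocks = blocks,
             if (!is.null(covariates)) c(covariates = covariates))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stopf("configuration references missing file(s): %s",
          paste(missing, collapse = ", "))
  stopifnot(all(structures %in% c("correlated", "bifactor")))
  structure(list(sumstats = sumstats, genotypes = genotypes, items = items,
                 blocks = blocks, covariates = covariates,
                 out_dir = out_dir, p_thresholds = p_thresholds,
                 structures = structures, min_per_block = min_per_block,
                 n_perm = n_perm, n_points = n_points, seed = seed,
                 compute_ic = compute_ic),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Side-by-side fit table for competing measurement structures
#'
#' @param fits named list of [fit_dwls()] results.
#' @param ics optional named list of [fit_marginal_ml()] results (same
#'   names).
#' @return data.frame with parameter counts, information criteria and
#'   absolute fit indices (RMSEA with 90 percent CI, CFI, TLI), one row
#'   per structure.
#' @export
fit_comparison_table <- function(fits, ics = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    fi <- compute_fit_indices(f)
    ic <- ics[[nm]]
    data.frame(
      model = nm, n_parameters = f$n_parameters,
      aic = ic$aic %||% NA_real_, bic = ic$bic %||% NA_real_,
      ssa_bic = ic$ssa_bic %||% NA_real_,
      rmsea = fi$rmsea, rmsea_90ci = fi$formatted,
      cfi = fi$cfi, tli = fi$tli, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) score each discovery trait at every P-value threshold;
#' (2) read items and apply the answered-items-per-block inclusion rule;
#' (3) fit the four measurement structures and build the comparison table
#' (information criteria by marginal likelihood when `compute_ic`);
#' (4) omega reliability from the bifactor solution; (5) per-trait
#' structural models (correlated and bifactor) at the primary threshold;
#' (6) max-T permutation-adjusted p-values on factor scores; (7) when
#' covariates are supplied, inverse-probability weighted refits. Every
#' output is stamped with the configuration hash, seeds and package
#' version; a stage failure aborts with the stage name, preserving
#' partial outputs on disk.
#'
#' @param config a [pipeline_config()] (or path to its YAML).
#' @return the report bundle (invisibly): list with `scores`,
#'   `fit_table`, `omegas`, `associations`, `permutation`, `ipw`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x) x), cfg_path)
  provenance <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bifactorPRS")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  log_msg <- function(...) message(sprintf(...))

  # 1. polygenic scores
  geno <- stage("genotypes", read_genotypes(config$genotypes))
  scores <- stage("prs", {
    lapply(config$sumstats, function(p) {
      ss <- read_summary_stats(p)
      score_prs(ss, geno, p_thresholds = config$p_thresholds)
    })
  })
  primary <- sprintf("PT_%g", config$p_thresholds[1L])
  primary_scores <- lapply(scores, `[[`, primary)
  if (length(primary_scores) >= 2L) {
    prs_cor <- prs_correlation_report(primary_scores)
    utils::write.csv(prs_cor,
                     file.path(config$out_dir, "prs_correlations.csv"))
  }
  for (tr in names(scores)) {
    prov <- list(trait = tr, n_snps = lapply(scores[[tr]], function(s)
      if (is.null(s)) 0L else attr(s, "n_snps")), provenance = provenance)
    jsonlite::write_json(prov,
                         file.path(config$out_dir,
                                   sprintf("prs_%s_provenance.json", tr)),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(scores[[tr]])) {
      s <- scores[[tr]][[nm]]
      if (!is.null(s))
        utils::write.csv(s, file.path(config$out_dir,
                                      sprintf("prs_%s_%s.csv", tr, nm)),
                         row.names = FALSE)
    }
  }
  log_msg("scored %d trait(s) at %d threshold(s)", length(scores),
          length(config$p_thresholds))

  # 2. items + inclusion rule
  blocks <- stage("blocks", read_blocks(config$blocks))
  items <- stage("items", read_items(config$items, blocks))
  items_f <- apply_inclusion_filter(items, config$min_per_block)
  rep <- attr(items_f, "filter_report")
  log_msg("inclusion filter: %d of %d respondents kept", rep$n_after,
          rep$n_before)

  # 3. measurement model comparison
  poly <- stage("polychoric", polychoric_matrix(items_f))
  fits <- stage("measurement", {
    lapply(setNames(MODEL_STRUCTURES, MODEL_STRUCTURES), function(st)
      fit_dwls(poly, build_model(st, blocks)))
  })
  ics <- NULL
  if (config$compute_ic) {
    ics <- stage("information_criteria", {
      lapply(fits, function(f)
        fit_marginal_ml(items_f, f, config$n_points,
                        seed = config$seed + 11L))
    })
  }
  fit_tab <- fit_comparison_table(fits, ics)
  utils::write.csv(fit_tab, file.path(config$out_dir, "fit_table.csv"),
                   row.names = FALSE)
  writeLines(c("Measurement model comparison",
               utils::capture.output(print(fit_tab, row.names = FALSE))),
             file.path(config$out_dir, "fit_table.txt"))

  # 4. reliability
  omegas <- stage("reliability", compute_omegas(fits$bifactor))
  jsonlite::write_json(
    c(list(omega = omegas$omega, omega_h = omegas$omega_h,
           omega_s = as.list(omegas$omega_s),
           omega_hs = as.list(omegas$omega_hs)),
      list(provenance = provenance)),
    file.path(config$out_dir, "omega.json"), auto_unbox = TRUE, digits = NA)

  # 5-6. structural associations + permutation sensitivity
  assoc <- list(); perm <- list()
  for (st in config$structures) {
    spec <- build_model(st, blocks)
    for (tr in names(primary_scores)) {
      sc <- primary_scores[[tr]]
      if (is.null(sc)) next
      key <- sprintf("%s_%s", tr, st)
      assoc[[key]] <- stage(paste0("association_", key),
                            fit_structural(items_f, sc, spec))
      fscores <- estimate_factor_scores(assoc[[key]], items_f)
      perm[[key]] <- stage(paste0("permutation_", key),
                           permutation_adjusted_p(
                             fscores, sc, n_perm = config$n_perm,
                             seed = config$seed + 23L))
    }
  }
  assoc_tab <- do.call(rbind, lapply(names(assoc), function(k) {
    f <- assoc[[k]]
    p <- perm[[k]]$table
    cbind(trait = sub("_[a-z]+$", "", k), model = f$model, f$table,
          p_adjusted = p$p_adjusted[match(f$table$outcome, p$outcome)])
  }))
  utils::write.csv(assoc_tab,
                   file.path(config$out_dir, "associations.csv"),
                   row.names = FALSE)

  # 7. IPW sensitivity
  ipw_out <- NULL
  if (!is.null(config$covariates)) {
    ipw_out <- stage("ipw", {
      cov <- read.csv(config$covariates, stringsAsFactors = FALSE)
      scored_ids <- primary_scores[[1L]]$id
      cov <- cov[match(scored_ids, cov$id), , drop = FALSE]
      included <- scored_ids %in% rownames(items_f)
      ipw <- estimate_ipw(included, cov)
      wtab <- do.call(rbind, lapply(names(assoc), function(k) {
        tr <- sub("_[a-z]+$", "", k)
        st <- sub("^.*_", "", k)
        f <- weighted_structural(items_f, primary_scores[[tr]],
                                 build_model(st, blocks), ipw)
        cbind(trait = tr, model = st, f$table)
      }))
      utils::write.csv(wtab,
                       file.path(config$out_dir,
                                 "associations_weighted.csv"),
                       row.names = FALSE)
      list(weights = ipw, table = wtab)
    })
  }

  bundle <- list(scores = scores, fit_table = fit_tab, fits = fits,
                 ics = ics, omegas = omegas, associations = assoc,
                 association_table = assoc_tab, permutation = perm,
                 ipw = ipw_out, provenance = provenance)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}
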