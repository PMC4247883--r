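#' Configuration of a full pipeline run
#'
#' @param panel_path,genotype_path,phenotype_path input files (see
#'   [load_inputs()]); alternatively supply `simulation` to generate the
#'   cohort instead of reading one.
#' @param simulation optional [simulation_config()]; when present the
#'   pipeline runs on a generated cohort and the paths are ignored.
#' @param weights optional panel weights for [read_panel()].
#' @param format_hint genotype format, "auto"/"tsv"/"vcf".
#' @param min_call_rate per-SNP call-rate threshold (default 0.95).
#' @param max_missing per-individual missing-genotype tolerance (default 3).
#' @param alpha family-wise error rate for QC flags (default 0.05).
#' @param adjustment_set covariates for all adjusted models.
#' @param bmi_adjustment_set additional adjustment set for waist/hip models
#'   (adds BMI to test mediation).
#' @param snp_exclusion_list SNPs removed in the sensitivity rerun; the
#'   default is the four panel SNPs with borderline Hardy-Weinberg p-values
#'   (set to `character()` to skip the rerun).
#' @param out_dir output directory, or NULL to skip writing files.
#' @param seed integer seed recorded in the run log (and driving the
#'   simulation when `simulation` is given without its own seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(panel_path = NULL, genotype_path = NULL,
                       phenotype_path = NULL, simulation = NULL,
                       weights = NULL, format_hint = "auto",
                       min_call_rate = 0.95, max_missing = 3, alpha = 0.05,
                       adjustment_set = c("age", "sex", "activity", "smoking"),
                       bmi_adjustment_set = c("age", "sex", "activity",
                                              "smoking", "bmi"),
                       snp_exclusion_list = c("rs3817334", "rs987237",
                                              "rs10968576", "rs4929949"),
                       out_dir = NULL, seed = NULL) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, max_missing >= 0,
            alpha > 0, alpha < 1)
  if (is.null(simulation) &&
      (is.null(panel_path) || is.null(genotype_path) || is.null(phenotype_path)))
    stop("supply either the three input paths or a simulation config")
  structure(list(panel_path = panel_path, genotype_path = genotype_path,
                 phenotype_path = phenotype_path, simulation = simulation,
                 weights = weights, format_hint = format_hint,
                 min_call_rate = min_call_rate, max_missing = max_missing,
                 alpha = alpha, adjustment_set = adjustment_set,
                 bmi_adjustment_set = bmi_adjustment_set,
                 snp_exclusion_list = snp_exclusion_list,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

assoc_row <- function(res, outcome, exposure) {
  data.frame(outcome = outcome, exposure = exposure, model = res$model,
             n = res$n, beta = res$beta, se = res$se, lcl = res$lcl,
             ucl = res$ucl, p = res$p, or_value = res$or_value,
             r2_crude = if (is.null(res$r2_percent)) NA_real_
                        else res$r2_percent[["crude"]],
             r2_full = if (is.null(res$r2_percent)) NA_real_
                       else res$r2_percent[["full"]],
             adjustment = paste(res$adjustment_set, collapse = "+"),
             row.names = NULL)
}

analyse_panel <- function(panel, genotypes, phenotypes, config) {
  qc <- qc_report(genotypes, panel, alpha = config$alpha,
                  min_rate = config$min_call_rate)
  kept_snps <- qc$snp_id[qc$kept]
  panel_kept <- gps_panel(as.data.frame(panel[panel$snp_id %in% kept_snps, ]),
                          name = attr(panel, "panel_name"))
  scores <- compute_gps(genotypes[, panel_kept$snp_id, drop = FALSE],
                        panel_kept, max_missing = config$max_missing)
  scored <- !scores$excluded
  gps <- scores$gps
  ph <- phenotypes
  covars <- ph[, intersect(c("age", "sex", "activity", "smoking", "bmi"),
                           names(ph)), drop = FALSE]

  traits <- list(bmi = "bmi", waist = "waist", hip = "hip", whr = "whr")
  rows <- list()
  for (tr in names(traits)) {
    res <- fit_linear(ph[[tr]][scored], gps[scored], covars[scored, ],
                      config$adjustment_set)
    rows[[length(rows) + 1]] <- assoc_row(res, tr, "gps")
    if (tr %in% c("waist", "hip", "whr")) {
      res_b <- fit_linear(ph[[tr]][scored], gps[scored], covars[scored, ],
                          config$bmi_adjustment_set)
      rows[[length(rows) + 1]] <- assoc_row(res_b, tr, "gps")
    }
  }
  trait_table <- do.call(rbind, rows)

  vardec <- explained_variance_decomposition(ph$bmi[scored], gps[scored],
                                             covars[scored, ],
                                             config$adjustment_set)

  # obesity analyses on normal-weight vs obese individuals only
  nonov <- scored & ph$bmi_class != "overweight"
  case <- ph$bmi_class[nonov] == "obese"
  obesity <- fit_logistic(case, gps[nonov], covars[nonov, ],
                          config$adjustment_set)
  quart <- quartile_or_analysis(gps[nonov], case, covars[nonov, ],
                                config$adjustment_set)

  per_snp <- do.call(rbind, lapply(panel_kept$snp_id, function(s) {
    res <- fit_linear(ph$bmi[scored], genotypes[scored, s], covars[scored, ],
                      config$adjustment_set)
    assoc_row(res, "bmi", s)
  }))
  direction <- direction_consistency(per_snp$beta)

  list(qc = qc, panel = panel_kept, scores = scores,
       trait_associations = trait_table, variance_decomposition = vardec,
       obesity = obesity, quartiles = quart, per_snp = per_snp,
       direction_consistency = direction)
}

#' Run the full score-association pipeline
#'
#' QC (call-rate filter, Hardy-Weinberg and reference-frequency tests),
#' score construction with mean-dosage imputation and the high-missingness
#' exclusion, covariate-adjusted trait associations (waist/hip/WHR also
#' under the BMI-added adjustment set), explained-variance decomposition,
#' the obesity logistic and quartile analyses on normal-weight versus obese
#' individuals (overweight removed inside the pipeline), per-SNP BMI
#' associations with the direction-consistency test, and - when
#' `snp_exclusion_list` is non-empty - the identical analysis bundle on the
#' reduced panel, whose rescaling renormalizes automatically. SNPs that
#' fail QC are never scored.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `full` and (when a
#'   sensitivity list is set) `sensitivity`, each as documented in the
#'   internals, plus `log` (seeds, thresholds, exclusion counts). When
#'   `out_dir` is set the tables are also written as tab-separated files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    if (is.null(sim$seed)) sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    panel <- cohort$panel
    genotypes <- cohort$genotypes
    phenotypes <- cohort$phenotypes
  } else {
    inputs <- load_inputs(config$panel_path, config$genotype_path,
                          config$phenotype_path, config$format_hint,
                          weights = config$weights)
    panel <- inputs$panel
    genotypes <- inputs$genotypes
    phenotypes <- inputs$phenotypes
  }

  full <- analyse_panel(panel, genotypes, phenotypes, config)

  sensitivity <- NULL
  excl <- intersect(config$snp_exclusion_list, panel$snp_id)
  if (length(excl)) {
    reduced <- gps_panel(as.data.frame(panel[!panel$snp_id %in% excl, ]),
                         name = paste0(attr(panel, "panel_name"), "-reduced"))
    sensitivity <- analyse_panel(reduced,
                                 genotypes[, reduced$snp_id, drop = FALSE],
                                 phenotypes, config)
  }

  log <- list(seed = config$seed,
              n_input = nrow(genotypes),
              n_snps_panel = nrow(panel),
              n_snps_kept = nrow(full$panel),
              n_excluded_individuals = sum(full$scores$excluded),
              min_call_rate = config$min_call_rate,
              max_missing = config$max_missing,
              alpha = config$alpha,
              hwe_threshold = attr(full$qc, "threshold"),
              snp_exclusion_list = excl)

  result <- structure(list(full = full, sensitivity = sensitivity, log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_bundle <- function(res, dir, prefix = "") {
  wr <- function(df, name) {
    utils::write.table(as.data.frame(df),
                       file.path(dir, paste0(prefix, name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  wr(res$qc, "qc_report")
  quart <- assign_quartiles(res$scores$gps)
  write_scores(res$scores, file.path(dir, paste0(prefix, "scores.tsv")),
               quartiles = quart)
  wr(res$trait_associations, "trait_associations")
  wr(data.frame(res$variance_decomposition), "variance_decomposition")
  qt <- as.data.frame(res$quartiles)
  qt$p_trend <- attr(res$quartiles, "p_trend")
  wr(qt, "quartile_or")
  wr(res$per_snp, "per_snp_associations")
  wr(data.frame(res$direction_consistency), "direction_consistency")
}

#' Write all pipeline tables to a directory
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bundle(result$full, dir)
  if (!is.null(result$sensitivity))
    write_bundle(result$sensitivity, dir, prefix = "sensitivity_")
  log <- result$log
  log$snp_exclusion_list <- paste(log$snp_exclusion_list, collapse = ",")
  log[vapply(log, is.null, logical(1))] <- "NA"
  writeLines(sprintf("%s\t%s", names(log), unlist(lapply(log, format))),
             file.path(dir, "run_log.tsv"))
  invisible(dir)
}
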