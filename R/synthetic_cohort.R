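#' Configuration of the synthetic cohort generator
#'
#' Bundles every parameter the generator needs, with defaults that emulate a
#' cross-sectional adult cohort of the kind the score analysis targets:
#' 787 adults aged 30-64, 52 percent women, genotypes in Hardy-Weinberg
#' equilibrium at the bundled panel frequencies with 5 percent missing
#' calls, BMI driven by the score at 0.15 kg/m2 per risk allele on top of a
#' covariate contribution of 13.1 percent of variance, total BMI standard
#' deviation 5.5 kg/m2, and an obesity outcome with a per-allele odds ratio
#' of 1.11 in logistic mode (or by thresholding BMI at 30 in threshold
#' mode).
#'
#' The variance budget is closed-form: with per-allele effect b and score
#' variance V_g under Hardy-Weinberg independence (computed from the panel
#' weights and frequencies), the genetic component contributes b^2 V_g; the
#' covariate coefficients are the `covariate_shape` rescaled so their
#' independent-covariate variance equals `covariate_r2 * bmi_total_sd^2`;
#' the residual noise variance is the remainder. A budget whose components
#' exceed the total is a configuration error.
#'
#' @param n cohort size.
#' @param panel a [gps_panel()] with weights and an `eaf` column used as
#'   simulation truth.
#' @param missing_rate per-cell genotype missingness probability.
#' @param max_missing exclusion rule carried into analyses.
#' @param bmi_per_allele BMI effect per risk allele, kg/m2.
#' @param bmi_mean,bmi_total_sd marginal BMI mean and SD, kg/m2.
#' @param covariate_r2 fraction of BMI variance due to covariates.
#' @param covariate_shape relative covariate effects (age per year, female,
#'   activity per level, current smoking), rescaled internally.
#' @param age_range,female_prob,smoking_probs,activity_probs covariate
#'   distributions.
#' @param disease_mode "logistic" (case status drawn from a logistic model
#'   in the score, so the target odds ratio is the true parameter) or
#'   "threshold" (obesity = simulated BMI at or above 30).
#' @param or_per_allele true per-allele obesity odds ratio (logistic mode).
#' @param disease_covariate_scale log-odds per kg/m2 of the covariate term
#'   carried into the disease model.
#' @param target_prevalence case prevalence the logistic intercept is
#'   solved for.
#' @param seed integer seed; the same config and seed give an identical
#'   cohort.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n = 787,
                              panel = isor_panel(synthetic_weights = TRUE),
                              missing_rate = 0.05,
                              max_missing = 3,
                              bmi_per_allele = 0.15,
                              bmi_mean = 26.5,
                              bmi_total_sd = 5.5,
                              covariate_r2 = 0.131,
                              covariate_shape = c(age = 0.08, female = -1,
                                                  activity = -0.8,
                                                  smoking = -1),
                              age_range = c(30, 64),
                              female_prob = 409 / 787,
                              smoking_probs = c(never = 0.55, former = 0.20,
                                                current = 0.25),
                              activity_probs = rep(0.25, 4),
                              disease_mode = c("logistic", "threshold"),
                              or_per_allele = 1.11,
                              disease_covariate_scale = 0.25,
                              target_prevalence = 0.33,
                              seed = NULL) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1,
            bmi_total_sd > 0, covariate_r2 >= 0, covariate_r2 < 1,
            or_per_allele > 0, target_prevalence > 0, target_prevalence < 1,
            inherits(panel, "gps_panel"))
  disease_mode <- match.arg(disease_mode)
  cfg <- list(n = n, panel = panel, missing_rate = missing_rate,
              max_missing = max_missing, bmi_per_allele = bmi_per_allele,
              bmi_mean = bmi_mean, bmi_total_sd = bmi_total_sd,
              covariate_r2 = covariate_r2, covariate_shape = covariate_shape,
              age_range = age_range, female_prob = female_prob,
              smoking_probs = smoking_probs, activity_probs = activity_probs,
              disease_mode = disease_mode, or_per_allele = or_per_allele,
              disease_covariate_scale = disease_covariate_scale,
              target_prevalence = target_prevalence, seed = seed)
  class(cfg) <- "simulation_config"
  budget <- variance_budget(cfg)  # errors if infeasible
  cfg$budget <- budget
  cfg
}

#' Theoretical score variance of a panel under Hardy-Weinberg independence
#'
#' Var(gps) = (2m / (2 sum(w)))^2 * sum(w_i^2 * 2 f_i (1 - f_i)) for a
#' panel of m independent SNPs with weights w and effect-allele
#' frequencies f.
#'
#' @param panel a [gps_panel()] with weights and `eaf`.
#' @return variance of the rescaled score, allele units squared.
#' @export
panel_gps_variance <- function(panel) {
  stopifnot(inherits(panel, "gps_panel"))
  if (is.null(panel$eaf) || anyNA(panel$eaf))
    stop("panel must carry an eaf column to compute the theoretical score variance")
  s <- panel_weight_sum(panel)
  v <- 2 * panel$eaf * (1 - panel$eaf)
  (nrow(panel) / s)^2 * sum(panel$weight^2 * v)
}

# Closed-form variance budget: genetic + covariate + noise = total.
variance_budget <- function(config) {
  total <- config$bmi_total_sd^2
  genetic <- config$bmi_per_allele^2 * panel_gps_variance(config$panel)
  cov_target <- config$covariate_r2 * total
  u <- config$covariate_shape
  p_act <- config$activity_probs / sum(config$activity_probs)
  act_mean <- sum(p_act * 0:3)
  vars <- c(age = diff(config$age_range)^2 / 12,
            female = config$female_prob * (1 - config$female_prob),
            activity = sum(p_act * (0:3 - act_mean)^2),
            smoking = config$smoking_probs[["current"]] *
              (1 - config$smoking_probs[["current"]]))
  var_u <- sum(u[names(vars)]^2 * vars)
  lambda <- if (cov_target == 0) 0 else sqrt(cov_target / var_u)
  noise <- total - genetic - cov_target
  if (noise <= 0)
    stop(sprintf(
      "infeasible variance budget: genetic %.2f + covariates %.2f exceed total %.2f",
      genetic, cov_target, total))
  list(total = total, genetic = genetic, covariates = cov_target,
       noise = noise, coefficients = lambda * u[names(vars)],
       covariate_means = c(age = mean(config$age_range),
                           female = config$female_prob,
                           activity = act_mean,
                           smoking = config$smoking_probs[["current"]]))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently as two allele draws at its panel
#' frequency (binomial(2, eaf)), so the matrix is in Hardy-Weinberg
#' equilibrium by construction, with no linkage disequilibrium.
#'
#' @param panel a [gps_panel()] with an `eaf` column.
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return complete integer genotype matrix, individuals x SNPs.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  stopifnot(inherits(panel, "gps_panel"), n >= 1)
  if (is.null(panel$eaf) || anyNA(panel$eaf))
    stop("panel must carry an eaf column to simulate genotypes")
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(panel$eaf, function(f) stats::rbinom(n, 2, f), integer(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  dimnames(g) <- list(sprintf("id%04d", seq_len(n)), panel$snp_id)
  g
}

#' Mask genotype calls at random
#'
#' Sets each cell to missing independently with probability `missing_rate`,
#' emulating a genotyping success rate of 1 - missing_rate.
#'
#' @param genotypes integer genotype matrix.
#' @param missing_rate per-cell missingness probability in [0, 1).
#' @param seed optional integer seed.
#' @return the matrix with NAs introduced.
#' @export
apply_missingness <- function(genotypes, missing_rate, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (missing_rate == 0) return(genotypes)
  mask <- matrix(stats::runif(length(genotypes)) < missing_rate,
                 nrow = nrow(genotypes))
  genotypes[mask] <- NA_integer_
  genotypes
}

#' Simulate the covariate part of a phenotype table
#'
#' Age uniform over the configured range, sex female with the configured
#' probability, smoking and four-level activity from their categorical
#' distributions.
#'
#' @param n number of individuals.
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return data.frame with individual_id, age, sex, smoking, activity.
#' @export
simulate_covariates <- function(n, config = simulation_config(n = n),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    individual_id = sprintf("id%04d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    sex = ifelse(stats::runif(n) < config$female_prob, "female", "male"),
    smoking = sample(names(config$smoking_probs), n, replace = TRUE,
                     prob = config$smoking_probs),
    activity = sample(activity_levels(), n, replace = TRUE,
                      prob = config$activity_probs),
    stringsAsFactors = FALSE)
}

# Linear covariate term of the BMI model, centred so it has mean ~0.
covariate_term <- function(covariates, config) {
  b <- config$budget
  co <- b$coefficients; mu <- b$covariate_means
  act <- as.numeric(factor(covariates$activity, levels = activity_levels())) - 1
  co[["age"]] * (covariates$age - mu[["age"]]) +
    co[["female"]] * ((covariates$sex == "female") - mu[["female"]]) +
    co[["activity"]] * (act - mu[["activity"]]) +
    co[["smoking"]] * ((covariates$smoking == "current") - mu[["smoking"]])
}

#' Simulate BMI from scores and covariates
#'
#' BMI = mean + b (gps - mean(gps)) + covariate term + Gaussian noise, with
#' coefficients and noise variance from the configuration's closed-form
#' variance budget. Weight and height are back-derived (height drawn per
#' sex, weight = BMI x height^2) so that [compute_bmi()] reproduces the
#' simulated BMI exactly; waist and hip circumferences are generated from
#' BMI alone (plus noise), which makes BMI the sole mediator of any
#' score-waist association.
#'
#' @param gps_values score in allele units (centred internally).
#' @param covariates covariate data.frame from [simulate_covariates()].
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return the covariate data.frame extended with weight, height, waist,
#'   hip and the derived bmi, whr, bmi_class columns.
#' @export
simulate_bmi <- function(gps_values, covariates, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  stopifnot(length(gps_values) == n)
  bmi <- config$bmi_mean +
    config$bmi_per_allele * (gps_values - mean(gps_values)) +
    covariate_term(covariates, config) +
    stats::rnorm(n, 0, sqrt(config$budget$noise))
  bmi <- pmax(bmi, 10)  # guard the (astronomically rare) non-physical tail
  height <- ifelse(covariates$sex == "female",
                   stats::rnorm(n, 1.62, 0.06), stats::rnorm(n, 1.75, 0.07))
  out <- covariates
  out$height <- round(height, 3)
  out$weight <- bmi * out$height^2   # unrounded so the Quetelet identity is exact
  out$waist <- round(30 + 2.4 * bmi + stats::rnorm(n, 0, 3), 1)
  out$hip <- round(50 + 1.9 * bmi + stats::rnorm(n, 0, 2.5), 1)
  derive_phenotypes(out)
}

#' Simulate obesity case status
#'
#' In logistic mode, P(case) = plogis(alpha + log(or_per_allele) (gps -
#' mean(gps)) + scaled covariate term), with alpha solved numerically so the
#' expected prevalence equals `target_prevalence`; the target odds ratio is
#' then the true conditional parameter. In threshold mode the label is
#' simply obesity of the supplied simulated BMI (at or above 30 kg/m2), and
#' overweight individuals should be excluded by the caller before
#' case-control analysis.
#'
#' @param gps_values score in allele units.
#' @param covariates covariate data.frame.
#' @param config a [simulation_config()].
#' @param bmi simulated BMI (required in threshold mode).
#' @param seed optional integer seed.
#' @return logical case indicator.
#' @export
simulate_obesity <- function(gps_values, covariates, config, bmi = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$disease_mode == "threshold") {
    if (is.null(bmi)) stop("threshold mode needs the simulated BMI")
    return(classify_bmi(bmi) == "obese")
  }
  eta <- log(config$or_per_allele) * (gps_values - mean(gps_values)) +
    config$disease_covariate_scale * covariate_term(covariates, config)
  f <- function(a) mean(stats::plogis(a + eta)) - config$target_prevalence
  sol <- tryCatch(stats::uniroot(f, c(-30, 30), tol = 1e-10),
                  error = function(e)
                    stop("target prevalence unreachable for this configuration"))
  stats::runif(length(eta)) < stats::plogis(sol$root + eta)
}

#' Generate a complete synthetic cohort
#'
#' Runs the whole generator under one seed: genotypes in Hardy-Weinberg
#' equilibrium at the panel frequencies, random per-cell missingness,
#' covariates, BMI driven by the *complete*-genotype score (missingness is
#' an observation process, not a biological one), and an obesity outcome.
#'
#' @param config a [simulation_config()]; its `seed` drives all stages.
#' @return list of class `synthetic_cohort` with elements `panel`,
#'   `genotypes` (with missingness), `genotypes_complete`, `phenotypes`
#'   (including case_status), `gps_true` (score from complete genotypes)
#'   and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  g_full <- simulate_genotypes(config$panel, config$n)
  g_obs <- apply_missingness(g_full, config$missing_rate)
  covars <- simulate_covariates(config$n, config)
  gps_true <- compute_gps(g_full, config$panel,
                          max_missing = config$max_missing)$gps
  pheno <- simulate_bmi(gps_true, covars, config)
  pheno$case_status <- simulate_obesity(gps_true, covars, config,
                                        bmi = pheno$bmi)
  structure(list(panel = config$panel, genotypes = g_obs,
                 genotypes_complete = g_full, phenotypes = pheno,
                 gps_true = gps_true, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits the panel, genotype and phenotype files that [load_inputs()] reads,
#' plus a key-value metadata file recording the seed and every scalar
#' generator parameter.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- as.data.frame(cohort$panel)
  utils::write.table(p, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_genotypes_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  keep <- setdiff(names(cohort$phenotypes),
                  c("bmi", "whr", "bmi_class", "case_status"))
  utils::write.table(cohort$phenotypes[, keep],
                     file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  cfg <- cohort$config
  scalars <- cfg[vapply(cfg, function(x)
    is.numeric(x) && length(x) == 1 || is.character(x) && length(x) == 1,
    logical(1))]
  meta <- c(sprintf("seed\t%s", if (is.null(cfg$seed)) "NA" else cfg$seed),
            sprintf("%s\t%s", names(scalars), unlist(scalars)))
  writeLines(meta, file.path(dir, "simulation_metadata.tsv"))
  invisible(dir)
}
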