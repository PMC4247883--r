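#' @importFrom stats lm glm binomial pchisq pnorm quantile coef vcov
NULL

# Build the model frame for an adjusted fit: exposure plus the requested
# covariates, with the package's standard encodings (sex female=1,
# smoking current=1 by default, activity as integer 0-3). Listwise deletion;
# the number of dropped rows is recorded.
build_design <- function(outcome, exposure, covariates, adjustment_set,
                         smoking_coding = c("binary", "three_level")) {
  smoking_coding <- match.arg(smoking_coding)
  stopifnot(length(outcome) == length(exposure))
  df <- data.frame(.y = outcome, exposure = exposure)
  for (v in adjustment_set) {
    if (is.null(covariates) || is.null(covariates[[v]]))
      stop("adjustment covariate not found: ", v)
    col <- covariates[[v]]
    if (length(col) != nrow(df)) stop("covariate length mismatch for ", v)
    df[[v]] <- switch(v,
      sex = as.numeric(col == "female"),
      smoking = if (smoking_coding == "binary") as.numeric(col == "current")
                else factor(col, levels = c("never", "former", "current")),
      activity = if (is.numeric(col)) col
                 else as.numeric(factor(col, levels = activity_levels())) - 1,
      col)
  }
  complete <- stats::complete.cases(df)
  structure(df[complete, , drop = FALSE], n_dropped = sum(!complete))
}

check_singular <- function(fit) {
  aliased <- is.na(coef(fit))
  if (any(aliased))
    stop("singular design: collinear column(s) ",
         paste(names(coef(fit))[aliased], collapse = ", "))
}

assoc_result <- function(outcome, exposure, model, fit, df, r2 = NULL) {
  est <- coef(fit)[["exposure"]]
  se <- sqrt(vcov(fit)["exposure", "exposure"])
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  res <- list(outcome = outcome, exposure = exposure, model = model,
              n = nrow(df), n_dropped = attr(df, "n_dropped"),
              beta = est, se = se,
              lcl = est - 1.96 * se, ucl = est + 1.96 * se, p = p,
              or_value = if (model == "logistic") exp(est) else NA_real_,
              or_lcl = if (model == "logistic") exp(est - 1.96 * se) else NA_real_,
              or_ucl = if (model == "logistic") exp(est + 1.96 * se) else NA_real_,
              r2_percent = r2,
              adjustment_set = setdiff(names(df), c(".y", "exposure")))
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s model: %s ~ %s  (n = %d)\n", x$model, x$outcome, x$exposure, x$n))
  if (x$model == "logistic")
    cat(sprintf("  OR per allele %.3f [%.3f - %.3f], p = %.2g\n",
                x$or_value, x$or_lcl, x$or_ucl, x$p))
  else
    cat(sprintf("  beta %.3f (SE %.3f) [%.3f - %.3f], p = %.2g\n",
                x$beta, x$se, x$lcl, x$ucl, x$p))
  if (!is.null(x$r2_percent))
    cat(sprintf("  explained variance: crude %.2f%%, full %.2f%%\n",
                x$r2_percent[["crude"]], x$r2_percent[["full"]]))
  if (length(x$adjustment_set))
    cat("  adjusted for:", paste(x$adjustment_set, collapse = ", "), "\n")
  invisible(x)
}

#' Covariate-adjusted linear association (additive genetic model)
#'
#' Ordinary least squares of a continuous trait on a per-allele exposure
#' (a genetic score or a single coded genotype), optionally adjusted for
#' covariates. Reports the per-allele slope with its Wald standard error,
#' symmetric 95 percent confidence interval and two-sided p-value, plus the
#' explained variance of the crude (exposure-only) and full models.
#'
#' @param outcome_values continuous trait.
#' @param exposure_values per-allele exposure (score in allele units or
#'   0/1/2 genotype).
#' @param covariates data.frame (or list) holding the adjustment columns.
#' @param adjustment_set character vector of covariate names (default none).
#' @param smoking_coding "binary" (current vs not, default) or "three_level".
#' @return an `assoc_result` (see [print.assoc_result()]).
#' @export
fit_linear <- function(outcome_values, exposure_values, covariates = NULL,
                       adjustment_set = character(),
                       smoking_coding = "binary") {
  df <- build_design(outcome_values, exposure_values, covariates,
                     adjustment_set, smoking_coding)
  if (nrow(df) <= length(adjustment_set) + 2)
    stop("too few complete cases for the requested model")
  fit <- lm(.y ~ ., data = df)
  check_singular(fit)
  crude <- lm(.y ~ exposure, data = df)
  r2 <- c(crude = 100 * summary(crude)$r.squared,
          full = 100 * summary(fit)$r.squared)
  assoc_result("outcome", "exposure", "linear", fit, df, r2)
}

#' Covariate-adjusted logistic association (additive genetic model)
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' per-allele exposure; reports the per-allele odds ratio with Wald 95
#' percent confidence limits.
#'
#' @param case_status binary outcome (logical or 0/1; TRUE/1 = case).
#' @param exposure_values per-allele exposure.
#' @inheritParams fit_linear
#' @return an `assoc_result` with `or_value`, `or_lcl`, `or_ucl`.
#' @export
fit_logistic <- function(case_status, exposure_values, covariates = NULL,
                         adjustment_set = character(),
                         smoking_coding = "binary") {
  y <- as.numeric(case_status)
  if (!all(y %in% c(0, 1) | is.na(y))) stop("case_status must be binary")
  df <- build_design(y, exposure_values, covariates, adjustment_set,
                     smoking_coding)
  if (length(unique(df$.y)) < 2) stop("both cases and controls are required")
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("logistic fit did not converge (separation detected)")
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("logistic fit did not converge")
  check_singular(fit)
  assoc_result("case_status", "exposure", "logistic", fit, df)
}

#' Obesity risk per quartile of the score
#'
#' Fits an adjusted logistic model with indicator-coded score quartiles
#' (quartile 1 as the reference, odds ratio fixed at 1), and a second model
#' with the quartile index entered as a single ordinal 0-3 term whose Wald
#' p-value is the p for trend. Callers analysing obesity should restrict
#' the input to normal-weight and obese individuals beforehand, since
#' overweight subjects belong to neither group.
#'
#' @param gps_values score in allele units.
#' @param case_status binary outcome (TRUE/1 = case).
#' @param covariates data.frame of adjustment columns.
#' @param adjustment_set covariate names (default none).
#' @param smoking_coding see [fit_linear()].
#' @return a `quartile_table`: data.frame with one row per quartile
#'   (n_controls, n_cases, or_value, lcl, ucl, p; reference row OR = 1) and
#'   attributes `p_trend` and `cut_points`.
#' @export
quartile_or_analysis <- function(gps_values, case_status, covariates = NULL,
                                 adjustment_set = character(),
                                 smoking_coding = "binary") {
  qa <- assign_quartiles(gps_values)
  y <- as.numeric(case_status)
  df <- build_design(y, gps_values, covariates, adjustment_set, smoking_coding)
  df$quartile <- qa$quartile[as.numeric(rownames(df))]
  counts <- table(factor(df$quartile, levels = 1:4),
                  factor(df$.y, levels = c(0, 1)))
  covars <- setdiff(names(df), c(".y", "exposure", "quartile"))
  rhs <- if (length(covars)) paste(c("qf", covars), collapse = " + ") else "qf"
  df$qf <- factor(df$quartile, levels = 1:4)
  fit_ind <- glm(stats::as.formula(paste(".y ~", rhs)), data = df,
                 family = binomial())
  df$qord <- df$quartile - 1
  rhs_tr <- if (length(covars)) paste(c("qord", covars), collapse = " + ") else "qord"
  fit_tr <- glm(stats::as.formula(paste(".y ~", rhs_tr)), data = df,
                family = binomial())
  est <- coef(fit_ind); V <- vcov(fit_ind)
  rows <- lapply(1:4, function(q) {
    if (q == 1)
      return(data.frame(quartile = 1, n_controls = counts[1, 1],
                        n_cases = counts[1, 2], or_value = 1,
                        lcl = NA_real_, ucl = NA_real_, p = NA_real_))
    term <- paste0("qf", q)
    undefined <- !(term %in% names(est)) || is.na(est[term]) ||
      counts[q, 1] == 0 || counts[q, 2] == 0
    if (undefined)
      return(data.frame(quartile = q, n_controls = counts[q, 1],
                        n_cases = counts[q, 2], or_value = NA_real_,
                        lcl = NA_real_, ucl = NA_real_, p = NA_real_))
    b <- est[[term]]; se <- sqrt(V[term, term])
    data.frame(quartile = q, n_controls = counts[q, 1], n_cases = counts[q, 2],
               or_value = exp(b), lcl = exp(b - 1.96 * se),
               ucl = exp(b + 1.96 * se), p = 2 * pnorm(-abs(b / se)))
  })
  tr_b <- coef(fit_tr)[["qord"]]
  tr_se <- sqrt(vcov(fit_tr)["qord", "qord"])
  structure(do.call(rbind, rows),
            class = c("quartile_table", "data.frame"),
            p_trend = 2 * pnorm(-abs(tr_b / tr_se)),
            or_trend = exp(tr_b),
            cut_points = qa$cut_points)
}

#' Explained-variance decomposition of a score
#'
#' R-squared (as percentages) of the crude model trait ~ score, of the full
#' model trait ~ score + covariates, and their difference, read as the share
#' of trait variance attributable to the covariates beyond the score.
#'
#' @inheritParams fit_linear
#' @param gps_values score in allele units.
#' @param adjustment_set covariate names for the full model.
#' @return list(r2_crude, r2_full, r2_covariables), all in percent.
#' @export
explained_variance_decomposition <- function(outcome_values, gps_values,
                                             covariates = NULL,
                                             adjustment_set = character(),
                                             smoking_coding = "binary") {
  res <- fit_linear(outcome_values, gps_values, covariates, adjustment_set,
                    smoking_coding)
  list(r2_crude = unname(res$r2_percent[["crude"]]),
       r2_full = unname(res$r2_percent[["full"]]),
       r2_covariables = unname(res$r2_percent[["full"]] -
                                 res$r2_percent[["crude"]]))
}

#' Direction consistency of per-SNP effects against a reference study
#'
#' Counts how many observed per-allele betas share the sign of the
#' reference (discovery) effects and tests the count against chance with an
#' exact one-sided binomial tail, P(X >= k | n, 1/2). Under effect-allele
#' coding all reference effects are positive by construction, so
#' consistency means a positive observed beta; a beta of exactly zero is
#' counted as inconsistent.
#'
#' @param observed_betas numeric vector of per-SNP effect estimates.
#' @param reference_directions vector of reference effect signs (+1/-1), or
#'   omitted for the all-positive effect-allele convention.
#' @param method "exact" (default) for the exact tail sum, or "normal" for
#'   the uncorrected normal approximation.
#' @return list(k_consistent, n, p_one_sided).
#' @examples
#' direction_consistency(c(0.5, 0.2, -0.1))  # k = 2 of 3
#' @export
direction_consistency <- function(observed_betas,
                                  reference_directions = NULL,
                                  method = c("exact", "normal")) {
  method <- match.arg(method)
  n <- length(observed_betas)
  if (is.null(reference_directions)) reference_directions <- rep(1, n)
  stopifnot(length(reference_directions) == n,
            all(reference_directions %in% c(-1, 1)))
  k <- sum(sign(observed_betas) == reference_directions)  # sign(0)=0: inconsistent
  p <- if (method == "exact") {
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    pnorm((k - n / 2) / sqrt(n / 4), lower.tail = FALSE)
  }
  list(k_consistent = k, n = n, p_one_sided = p)
}
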