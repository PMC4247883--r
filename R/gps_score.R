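#' Mean effect-allele dosage of a SNP
#'
#' Arithmetic mean of the non-missing coded genotypes, used to impute
#' missing calls; algebraically equal to twice the effect-allele frequency.
#'
#' @param genotypes integer genotype matrix.
#' @param snp_id column to average.
#' @return dosage in [0, 2].
#' @export
mean_allele_count <- function(genotypes, snp_id) {
  if (!snp_id %in% colnames(genotypes)) stop("unknown snp_id: ", snp_id)
  g <- genotypes[, snp_id]
  if (all(is.na(g)))
    stop("all calls missing for ", snp_id,
         " (should have been removed by the call-rate filter)")
  mean(g, na.rm = TRUE)
}

#' Exclude individuals with too many missing genotypes
#'
#' An individual is excluded from score analyses when more than
#' `max_missing` of their panel genotypes are missing (the default keeps
#' individuals with up to 3 missing SNPs).
#'
#' @param genotypes integer genotype matrix restricted to the scored SNPs.
#' @param max_missing largest tolerated number of missing genotypes.
#' @return list with `kept` and `excluded` individual ids and the
#'   per-individual `n_missing` vector.
#' @export
exclude_high_missing <- function(genotypes, max_missing = 3) {
  stopifnot(max_missing >= 0)
  n_missing <- rowSums(is.na(genotypes))
  list(kept = rownames(genotypes)[n_missing <= max_missing],
       excluded = rownames(genotypes)[n_missing > max_missing],
       n_missing = n_missing)
}

#' Weighted raw score for one genotype row
#'
#' Sum over panel SNPs of the per-allele weight times the coded genotype,
#' with missing genotypes replaced by the supplied imputation dosages.
#'
#' @param genotype_row integer vector named by snp_id (NA = missing).
#' @param panel a [gps_panel()] with weights.
#' @param imputation_means named dosage vector covering at least the SNPs
#'   missing in this row (see [mean_allele_count()]).
#' @return raw score in kg/m2.
#' @export
weighted_score <- function(genotype_row, panel, imputation_means = NULL) {
  stopifnot(inherits(panel, "gps_panel"))
  g <- genotype_row[panel$snp_id]
  miss <- is.na(g)
  if (any(miss)) {
    need <- panel$snp_id[miss]
    if (is.null(imputation_means) || !all(need %in% names(imputation_means)))
      stop("no imputation mean available for: ",
           paste(setdiff(need, names(imputation_means)), collapse = ", "))
    g[miss] <- imputation_means[need]
  }
  sum(panel$weight * g)
}

#' Rescale a raw weighted score to risk-allele units
#'
#' The raw score has maximum twice the weight sum; dividing by that maximum
#' and multiplying by twice the panel size (the number of alleles) puts the
#' score on a 0..2m scale where each point corresponds to one risk allele.
#' For a 29-SNP panel whose weights sum to 4.12 this is the divide-by-8.24,
#' multiply-by-58 rescaling; a reduced panel renormalizes automatically.
#'
#' @param raw_score raw score(s) in kg/m2.
#' @param panel a [gps_panel()] with weights.
#' @return score(s) in allele units, in [0, 2 * nrow(panel)].
#' @examples
#' p <- isor_panel(synthetic_weights = TRUE)
#' rescale_score(2 * panel_weight_sum(p), p)  # 58
#' @export
rescale_score <- function(raw_score, panel) {
  s <- panel_weight_sum(panel)
  raw_score / (2 * s) * (2 * nrow(panel))
}

#' Compute genetic predisposition scores for a cohort
#'
#' Codes each individual's genotypes as effect-allele counts, imputes
#' missing calls with the per-SNP mean dosage, excludes individuals with
#' more than `max_missing` missing genotypes, weights and sums, and rescales
#' to allele units. Imputation dosages are computed from the full genotyped
#' sample before the individual exclusion (set
#' `impute_after_exclusion = TRUE` to compute them from the retained
#' individuals only).
#'
#' @param genotypes integer genotype matrix; its columns must exactly cover
#'   the panel SNPs.
#' @param panel a [gps_panel()] with weights.
#' @param max_missing exclusion rule, see [exclude_high_missing()].
#' @param impute_after_exclusion compute imputation means on retained
#'   individuals instead of the full sample.
#' @return a data.frame of class `gps_result` with one row per individual:
#'   individual_id, n_missing, excluded, raw_score, gps (NA when excluded).
#' @export
compute_gps <- function(genotypes, panel, max_missing = 3,
                        impute_after_exclusion = FALSE) {
  stopifnot(inherits(panel, "gps_panel"))
  absent <- setdiff(panel$snp_id, colnames(genotypes))
  if (length(absent))
    stop("genotype matrix lacks panel SNP(s): ", paste(absent, collapse = ", "))
  g <- genotypes[, panel$snp_id, drop = FALSE]
  excl <- exclude_high_missing(g, max_missing)
  base <- if (impute_after_exclusion) g[excl$kept, , drop = FALSE] else g
  imput <- vapply(panel$snp_id, function(s) mean_allele_count(base, s),
                  numeric(1))
  w <- panel$weight
  if (anyNA(w)) stop("panel has missing weights")
  gi <- g
  for (s in panel$snp_id) {
    col <- gi[, s]
    col[is.na(col)] <- imput[s]
    gi[, s] <- col
  }
  raw <- as.numeric(gi %*% w)
  gps <- rescale_score(raw, panel)
  excluded <- rownames(g) %in% excl$excluded
  raw[excluded] <- NA_real_
  gps[excluded] <- NA_real_
  structure(data.frame(individual_id = rownames(g),
                       n_missing = excl$n_missing,
                       excluded = excluded,
                       raw_score = raw, gps = gps,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gps_result", "data.frame"),
            imputation_means = imput)
}

#' Assign score quartiles
#'
#' Cut points are the empirical 25/50/75 percentiles of the supplied scores;
#' assignment uses half-open intervals, a value exactly at a cut point going
#' to the upper quartile, and the top quartile closed above.
#'
#' @param gps_values numeric scores (NAs allowed, assigned NA).
#' @return list of class `quartile_assignment` with `cut_points` (length 3)
#'   and `quartile` (integer 1-4 per value).
#' @export
assign_quartiles <- function(gps_values) {
  obs <- gps_values[!is.na(gps_values)]
  if (length(unique(obs)) < 4)
    stop("need at least 4 distinct score values to form quartiles")
  cuts <- unname(stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7))
  if (any(diff(cuts) <= 0))
    stop("degenerate quartile cut points (ties at the quartile boundaries)")
  q <- findInterval(gps_values, cuts, left.open = FALSE) + 1L
  q[is.na(gps_values)] <- NA_integer_
  structure(list(cut_points = cuts, quartile = q),
            class = "quartile_assignment")
}

#' Write a score table as tab-separated text
#' @param scores a `gps_result` data.frame from [compute_gps()].
#' @param path output path.
#' @param quartiles optional [assign_quartiles()] result to append.
#' @export
write_scores <- function(scores, path, quartiles = NULL) {
  out <- as.data.frame(scores)
  if (!is.null(quartiles)) out$quartile <- quartiles$quartile
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
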