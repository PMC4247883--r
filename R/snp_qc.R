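#' Genotype counts for one SNP
#'
#' Counts of individuals carrying 0, 1 and 2 copies of the effect allele,
#' over non-missing calls only.
#'
#' @param genotypes integer genotype matrix (individuals x SNPs).
#' @param snp_id column to count.
#' @return named integer vector c(n0, n1, n2).
#' @export
genotype_counts <- function(genotypes, snp_id) {
  if (!snp_id %in% colnames(genotypes))
    stop("unknown snp_id: ", snp_id)
  g <- genotypes[, snp_id]
  c(n0 = sum(g == 0L, na.rm = TRUE),
    n1 = sum(g == 1L, na.rm = TRUE),
    n2 = sum(g == 2L, na.rm = TRUE))
}

#' Effect-allele frequency from genotype counts
#'
#' @param counts numeric vector (n0, n1, n2) of genotype counts.
#' @return (n1 + 2 n2) / (2 n).
#' @examples
#' effect_allele_frequency(c(278, 370, 106))  # 0.386
#' @export
effect_allele_frequency <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("cannot compute an allele frequency from zero calls")
  unname((counts[2] + 2 * counts[3]) / (2 * n))
}

check_counts <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 3)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  counts
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Pearson 1-df goodness-of-fit chi-square of the observed genotype counts
#' against the proportions ((1-f)^2, 2f(1-f), f^2) expected under
#' Hardy-Weinberg equilibrium at the sample effect-allele frequency f, with
#' no continuity correction. `method = "exact"` instead returns the exact
#' test of Wigginton, Cutler & Abecasis (2005), whose p-value is the summed
#' probability of all heterozygote counts no more likely than the observed
#' one, conditional on the allele counts. Monomorphic SNPs (f equal to 0 or
#' 1) show no measurable departure and return chi2 = 0, p = 1.
#'
#' @param counts numeric vector (n0, n1, n2).
#' @param method "chi2" (default) or "exact".
#' @return a one-row data.frame of class `hwe_result` with columns n0, n1,
#'   n2, n, eaf, chi2 (NA for the exact test), df, p.
#' @examples
#' hwe_test(c(278, 370, 106))$p   # 0.33
#' @export
hwe_test <- function(counts, method = c("chi2", "exact")) {
  method <- match.arg(method)
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("cannot test HWE with zero calls")
  f <- effect_allele_frequency(counts)
  if (f == 0 || f == 1) {
    chi2 <- 0; p <- 1
  } else if (method == "chi2") {
    expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    chi2 <- sum((counts - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- hwe_exact_p(counts)
  }
  structure(data.frame(n0 = counts[1], n1 = counts[2], n2 = counts[3],
                       n = n, eaf = f, chi2 = chi2, df = 1L, p = p,
                       row.names = NULL),
            class = c("hwe_result", "data.frame"))
}

# Exact HWE p (Wigginton et al. 2005): probabilities of heterozygote counts
# conditional on the allele counts, summed over outcomes <= observed.
hwe_exact_p <- function(counts) {
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  n <- n0 + n1 + n2
  n_rare <- min(n1 + 2 * n0, n1 + 2 * n2)  # copies of the rarer allele
  het_vals <- seq.int(n_rare %% 2, n_rare, by = 2)
  # unnormalized probabilities via the standard recurrence, from mid-range
  probs <- numeric(length(het_vals))
  mid <- which.min(abs(het_vals - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid] <- 1
  if (mid < length(het_vals)) {
    for (k in mid:(length(het_vals) - 1)) {
      h <- het_vals[k]
      rare_hom <- (n_rare - h) / 2
      common_hom <- n - h - rare_hom
      probs[k + 1] <- probs[k] * 4 * rare_hom * common_hom /
        ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      h <- het_vals[k]
      rare_hom <- (n_rare - h) / 2
      common_hom <- n - h - rare_hom
      probs[k - 1] <- probs[k] * h * (h - 1) /
        (4 * (rare_hom + 1) * (common_hom + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[het_vals == n1]
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Filter panel SNPs on genotyping call rate
#'
#' @param genotypes integer genotype matrix restricted to panel SNPs.
#' @param panel a [gps_panel()].
#' @param min_rate minimum fraction of non-missing calls to keep a SNP
#'   (default 0.95; the boundary itself is kept).
#' @return list with `kept` (snp ids), `dropped` (snp ids) and `rates`
#'   (named call-rate vector over all panel SNPs present).
#' @export
call_rate_filter <- function(genotypes, panel, min_rate = 0.95) {
  stopifnot(inherits(panel, "gps_panel"), min_rate >= 0, min_rate <= 1)
  snps <- intersect(panel$snp_id, colnames(genotypes))
  if (!length(snps)) stop("no panel SNPs present in the genotype matrix")
  rates <- colMeans(!is.na(genotypes[, snps, drop = FALSE]))
  list(kept = snps[rates >= min_rate],
       dropped = snps[rates < min_rate],
       rates = rates)
}

#' Compare an observed allele distribution with a reference frequency
#'
#' One-df Pearson goodness-of-fit chi-square of the observed allele counts
#' (2n f_obs effect alleles, 2n (1 - f_obs) other alleles) against the
#' reference proportions. Used to flag SNPs whose cohort frequency differs
#' from the discovery population's.
#'
#' @param counts genotype counts (n0, n1, n2).
#' @param reference_eaf reference effect-allele frequency, strictly in (0,1).
#' @return list(chi2, df = 1, p).
#' @export
compare_allele_distribution <- function(counts, reference_eaf) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("cannot compare allele distributions with zero calls")
  if (is.na(reference_eaf) || reference_eaf <= 0 || reference_eaf >= 1)
    stop("reference_eaf must lie strictly inside (0, 1)")
  f_obs <- effect_allele_frequency(counts)
  observed <- c(2 * n * f_obs, 2 * n * (1 - f_obs))
  expected <- 2 * n * c(reference_eaf, 1 - reference_eaf)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param m number of independent tests (>= 1).
#' @return alpha / m.
#' @examples
#' bonferroni_threshold(0.05, 29)  # 0.0017
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Per-SNP quality-control report
#'
#' One row per panel SNP: genotype counts and fractions, call rate,
#' effect-allele frequency, HWE test, and (where a reference frequency is
#' available) the allele-distribution comparison against the reference
#' population. SNPs failing the call-rate filter are reported but carry
#' `kept = FALSE`; the Bonferroni threshold uses alpha over the number of
#' SNPs that survive the filter.
#'
#' @param genotypes integer genotype matrix.
#' @param panel a [gps_panel()].
#' @param alpha family-wise error rate for the HWE and frequency flags.
#' @param min_rate call-rate threshold (see [call_rate_filter()]).
#' @param hwe_method "chi2" or "exact", see [hwe_test()].
#' @return a data.frame of class `qc_report`, one row per panel SNP, with
#'   attribute `threshold` (the Bonferroni-corrected p threshold).
#' @export
qc_report <- function(genotypes, panel, alpha = 0.05, min_rate = 0.95,
                      hwe_method = c("chi2", "exact")) {
  hwe_method <- match.arg(hwe_method)
  cr <- call_rate_filter(genotypes, panel, min_rate)
  snps <- intersect(panel$snp_id, colnames(genotypes))
  thr <- bonferroni_threshold(alpha, length(cr$kept))
  rows <- lapply(snps, function(s) {
    cts <- genotype_counts(genotypes, s)
    h <- hwe_test(cts, method = hwe_method)
    prow <- panel[panel$snp_id == s, ]
    ref <- if (!is.null(prow$ref_eaf)) prow$ref_eaf else NA_real_
    fd <- if (!is.na(ref) && ref > 0 && ref < 1 && sum(cts) > 0)
      compare_allele_distribution(cts, ref)$p else NA_real_
    data.frame(snp_id = s, locus = if (!is.null(prow$locus)) prow$locus else NA,
               effect_allele = prow$effect_allele, other_allele = prow$other_allele,
               n0 = cts[1], n1 = cts[2], n2 = cts[3], n = h$n,
               call_rate = unname(cr$rates[s]), kept = s %in% cr$kept,
               eaf = h$eaf, ref_eaf = ref,
               hwe_chi2 = h$chi2, hwe_p = h$p,
               hwe_flag = h$p <= thr,
               freq_diff_p = fd,
               freq_diff_flag = !is.na(fd) & fd <= thr,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("qc_report", "data.frame"),
            threshold = thr, alpha = alpha, min_rate = min_rate)
}

#' Write a QC report as a tab-separated table
#' @param report a [qc_report()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
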