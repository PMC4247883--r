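#' SNP panel objects
#'
#' A panel is the definition of the score: one row per SNP with its effect
#' allele (the BMI-raising allele whose copies are counted 0/1/2), the other
#' allele, a per-allele weight in kg/m2 (the published beta coefficient), and
#' optionally the effect-allele frequency reported by the discovery study
#' (`ref_eaf`) and a frequency used as simulation truth (`eaf`).
#'
#' @param x a data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `weight` and optionally `locus`, `ref_eaf`, `eaf`.
#' @param name a label for the panel.
#' @return an object of class `gps_panel` (a validated data.frame).
#' @examples
#' gps_panel(data.frame(snp_id = c("rs1", "rs2"),
#'                      effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'                      weight = c(0.2, 0.1)))
#' @export
gps_panel <- function(x, name = "panel") {
  stopifnot(is.data.frame(x))
  required <- c("snp_id", "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  x$snp_id <- as.character(x$snp_id)
  if (anyDuplicated(x$snp_id))
    stop("duplicate snp_id in panel: ",
         paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
  if (nrow(x) < 1) stop("panel must contain at least one SNP")
  bases <- c("A", "C", "G", "T")
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  if (!all(x$effect_allele %in% bases) || !all(x$other_allele %in% bases))
    stop("alleles must be one of A/C/G/T")
  same <- x$effect_allele == x$other_allele
  if (any(same))
    stop("effect and other allele identical for: ",
         paste(x$snp_id[same], collapse = ", "))
  if (!all(is.na(x$weight) | x$weight >= 0))
    stop("weights must be non-negative")
  for (col in c("ref_eaf", "eaf")) {
    if (!is.null(x[[col]])) {
      bad <- !is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1)
      if (any(bad)) stop(col, " outside [0,1] for: ",
                         paste(x$snp_id[bad], collapse = ", "))
    }
  }
  structure(x, class = c("gps_panel", "data.frame"), panel_name = name)
}

#' Read a SNP panel from a tab-separated file
#'
#' The file must have a header with at least
#' `snp_id locus effect_allele other_allele weight ref_eaf` (extra columns
#' such as `eaf` are kept). Missing weights may be written as `NA` and
#' supplied later via the `weights` argument or [set_panel_weights()].
#'
#' @param path path to the panel TSV.
#' @param weights optional numeric vector of per-allele weights, either named
#'   by snp_id or in panel row order.
#' @param name panel label (defaults to the file name).
#' @return a [gps_panel()] object.
#' @export
read_panel <- function(path, weights = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  p <- gps_panel(x, name = name)
  if (!is.null(weights)) p <- set_panel_weights(p, weights)
  p
}

#' Set or replace the per-allele weights of a panel
#'
#' @param panel a [gps_panel()].
#' @param weights numeric vector, named by snp_id or in panel order.
#' @return the panel with weights filled in.
#' @export
set_panel_weights <- function(panel, weights) {
  stopifnot(inherits(panel, "gps_panel"), is.numeric(weights))
  if (!is.null(names(weights))) {
    missing_w <- setdiff(panel$snp_id, names(weights))
    if (length(missing_w))
      stop("no weight supplied for: ", paste(missing_w, collapse = ", "))
    panel$weight <- unname(weights[panel$snp_id])
  } else {
    if (length(weights) != nrow(panel))
      stop("expected ", nrow(panel), " weights, got ", length(weights))
    panel$weight <- weights
  }
  gps_panel(as.data.frame(panel), name = attr(panel, "panel_name"))
}

#' Sum of panel weights
#'
#' Twice this sum is the raw-score maximum (every SNP homozygous for the
#' effect allele) and the divisor of the allele-unit rescaling; for the
#' 29-SNP obesity panel it equals 8.24/2 = 4.12.
#'
#' @param panel a [gps_panel()].
#' @return numeric scalar, the sum of the per-allele weights.
#' @export
panel_weight_sum <- function(panel) {
  stopifnot(inherits(panel, "gps_panel"))
  w <- panel$weight
  if (anyNA(w)) stop("panel has missing weights; supply them with set_panel_weights()")
  s <- sum(w)
  if (s <= 0) stop("panel weight sum must be positive")
  s
}

#' The 29-SNP obesity panel of the ISOR study
#'
#' Effect/other alleles, reference (discovery-study) effect-allele
#' frequencies and the observed cohort effect-allele frequencies of the 29
#' BMI-associated SNPs analysed in the ISOR population sample. Per-allele
#' weights are not part of the published record, so `weight` is `NA` unless
#' `weights` is supplied or `synthetic_weights = TRUE`, which attaches a
#' bundled *synthetic* weight set: 29 positive values constructed for
#' simulation work so that they sum to 4.12 (twice the sum = 8.24) and give
#' the rescaled score a standard deviation of 3.7 allele units under
#' Hardy-Weinberg independence at the panel frequencies. The synthetic
#' weights are not the discovery-study betas.
#'
#' @param weights optional numeric weights (see [set_panel_weights()]).
#' @param synthetic_weights attach the bundled synthetic weight set.
#' @return a [gps_panel()] of 29 SNPs.
#' @examples
#' p <- isor_panel(synthetic_weights = TRUE)
#' nrow(p)              # 29
#' 2 * panel_weight_sum(p)  # 8.24
#' @export
isor_panel <- function(weights = NULL, synthetic_weights = FALSE) {
  p <- read_panel(system.file("extdata", "isor_panel.tsv", package = "gpsassoc"),
                  name = "ISOR-29")
  if (!is.null(weights) && synthetic_weights)
    stop("supply either explicit weights or synthetic_weights = TRUE, not both")
  if (synthetic_weights) {
    w <- utils::read.table(system.file("extdata", "synthetic_weights.tsv",
                                       package = "gpsassoc"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    p <- set_panel_weights(p, stats::setNames(w$weight, w$snp_id))
  } else if (!is.null(weights)) {
    p <- set_panel_weights(p, weights)
  }
  p
}

#' Genotype counts of the ISOR panel SNPs
#'
#' The published per-SNP genotype counts (number of individuals carrying
#' 0, 1 or 2 copies of the effect allele) for the 29 panel SNPs.
#'
#' @return a data.frame with columns snp_id, n0, n1, n2.
#' @export
isor_genotype_counts <- function() {
  utils::read.table(system.file("extdata", "isor_genotype_counts.tsv",
                                package = "gpsassoc"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @export
print.gps_panel <- function(x, ...) {
  cat("SNP panel '", attr(x, "panel_name"), "': ", nrow(x), " SNPs",
      sep = "")
  if (!anyNA(x$weight))
    cat(", weight sum ", format(sum(x$weight)), sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
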