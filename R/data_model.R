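#' @importFrom stats setNames
NULL

MISSING_TOKENS <- c("NA", ".", "./.", ".|.", "")

#' Read a genotype matrix from the tab-separated dialect
#'
#' First column `individual_id`, remaining columns named by snp_id, cells in
#' \{0, 1, 2\} counting copies of the effect allele; `NA`, `.`, `./.` or an
#' empty cell mark a missing genotype.
#'
#' @param path path to the genotype TSV.
#' @return an integer matrix (individuals x SNPs) with NA for missing calls,
#'   rownames = individual ids, colnames = snp ids.
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (names(x)[1] != "individual_id")
    stop("first column of a genotype table must be 'individual_id'")
  ids <- x$individual_id
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  snps <- names(x)[-1]
  if (anyDuplicated(snps))
    stop("duplicate snp ids in genotype header")
  g <- as.matrix(x[, -1, drop = FALSE])
  g[g %in% MISSING_TOKENS] <- NA
  bad <- !is.na(g) & !(g %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' for individual '%s', SNP '%s'",
                 g[bad][1], ids[idx[1]], snps[idx[2]]))
  }
  storage.mode(g) <- "integer"
  dimnames(g) <- list(ids, snps)
  g
}

#' Write a genotype matrix in the tab-separated dialect
#'
#' Inverse of [read_genotypes_tsv()]; reading then writing is byte-stable.
#'
#' @param genotypes integer matrix as returned by [read_genotypes_tsv()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes),
                   genotypes, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read genotypes from a VCF and orient them to a panel's effect alleles
#'
#' Accepts standard VCF 4.x with a GT field, bi-allelic records only. The
#' panel is authoritative for orientation: for each SNP the genotype is
#' recoded to the number of copies of the panel's effect allele, whichever
#' of REF/ALT it is. Strand flips are not resolved: a panel SNP whose
#' \{effect, other\} alleles do not equal the record's \{REF, ALT\} set is an
#' error, because silent strand guessing corrupts scores.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param panel a [gps_panel()]; only panel SNPs found in the VCF are kept.
#' @return integer matrix of effect-allele counts, individuals x SNPs.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  stopifnot(inherits(panel, "gps_panel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  ids <- fix[, "ID"]
  keep <- which(ids %in% panel$snp_id)
  if (!length(keep)) stop("no panel SNPs found in VCF ", path)
  multi <- grepl(",", fix[keep, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF record(s) not supported: ",
         paste(ids[keep][multi], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  alt_counts <- function(x) {
    x[is.na(x) | x %in% MISSING_TOKENS] <- NA
    alleles <- strsplit(x, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "."))
        return(NA_integer_)
      if (!all(a %in% c("0", "1")))
        stop("unexpected allele index in GT field: ", paste(a, collapse = "/"))
      sum(a == "1")
    }, integer(1))
  }
  out <- matrix(NA_integer_, nrow = ncol(gt), ncol = length(keep),
                dimnames = list(colnames(gt), ids[keep]))
  for (j in seq_along(keep)) {
    snp <- ids[keep][j]
    prow <- panel[panel$snp_id == snp, ]
    ref <- fix[keep[j], "REF"]; alt <- fix[keep[j], "ALT"]
    ac <- alt_counts(gt[j, ])
    if (prow$effect_allele == alt && prow$other_allele == ref) {
      out[, j] <- ac
    } else if (prow$effect_allele == ref && prow$other_allele == alt) {
      out[, j] <- 2L - ac
    } else {
      stop(sprintf(
        "allele mismatch for %s: panel %s/%s vs VCF REF/ALT %s/%s (strand flips are not auto-resolved)",
        snp, prow$effect_allele, prow$other_allele, ref, alt))
    }
  }
  out
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with columns `individual_id`, `age` (years), `sex`
#' (male/female), `smoking` (never/former/current), `activity`
#' (none/low/medium/high), `weight` (kg), `height` (m), `waist` (cm),
#' `hip` (cm). Derived columns `bmi` (Quetelet equation), `whr`
#' (waist/hip) and `bmi_class` are added on read.
#'
#' @param path path to the phenotype TSV.
#' @return a data.frame with derived anthropometric columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  derive_phenotypes(x)
}

#' Add derived anthropometric columns to a phenotype table
#'
#' @param x data.frame with at least individual_id, weight, height; sex,
#'   smoking and activity are validated and encoded if present.
#' @return the table with bmi, whr and bmi_class columns.
#' @export
derive_phenotypes <- function(x) {
  stopifnot(is.data.frame(x), "individual_id" %in% names(x))
  x$individual_id <- as.character(x$individual_id)
  if (anyDuplicated(x$individual_id))
    stop("duplicate individual ids in phenotype table")
  if (!is.null(x$sex)) {
    bad <- !x$sex %in% c("male", "female")
    if (any(bad)) stop("sex must be male/female; offending rows: ",
                       paste(which(bad), collapse = ", "))
  }
  if (!is.null(x$smoking) && !all(x$smoking %in% c("never", "former", "current")))
    stop("smoking must be never/former/current")
  if (!is.null(x$activity) && !all(x$activity %in% activity_levels()))
    stop("activity must be one of ", paste(activity_levels(), collapse = "/"))
  if (!is.null(x$weight) && !is.null(x$height)) {
    x$bmi <- compute_bmi(x$weight, x$height)
    x$bmi_class <- classify_bmi(x$bmi)
  }
  if (!is.null(x$waist) && !is.null(x$hip)) {
    if (any(x$waist <= 0 | x$hip <= 0, na.rm = TRUE))
      stop("waist and hip circumferences must be positive")
    x$whr <- x$waist / x$hip
  }
  x
}

#' Physical-activity levels, lowest to highest
#' @return character vector of the four ordered levels.
#' @export
activity_levels <- function() c("none", "low", "medium", "high")

#' Body-mass index (Quetelet equation)
#'
#' @param weight_kg body weight in kilograms.
#' @param height_m standing height in metres.
#' @return BMI in kg/m2 (vectorised).
#' @examples
#' compute_bmi(70, 1.70)    # 24.22
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' WHO BMI class
#'
#' Normal weight below 25 kg/m2, overweight in [25, 30), obese at or above
#' 30 kg/m2 (half-open boundaries).
#'
#' @param bmi BMI in kg/m2.
#' @return factor with levels normal/overweight/obese.
#' @export
classify_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be positive")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

#' Load and align panel, genotype and phenotype inputs
#'
#' Reads the three input files, orients genotypes to the panel's effect
#' alleles (VCF REF/ALT polarity resolved per SNP), restricts the genotype
#' matrix to panel SNPs, and aligns individuals present in both the genotype
#' and phenotype tables. Unmatched records are reported via a message and
#' returned in the `unmatched` element.
#'
#' @param panel_path path to the panel TSV (or a ready [gps_panel()]).
#' @param genotype_path path to a genotype TSV or VCF.
#' @param phenotype_path path to the phenotype TSV.
#' @param format_hint "tsv", "vcf" or "auto" (by file extension).
#' @param weights optional panel weights passed to [read_panel()].
#' @return list with elements `panel`, `genotypes`, `phenotypes`,
#'   `unmatched` (list of ids present in only one table).
#' @export
load_inputs <- function(panel_path, genotype_path, phenotype_path,
                        format_hint = c("auto", "tsv", "vcf"),
                        weights = NULL) {
  format_hint <- match.arg(format_hint)
  panel <- if (inherits(panel_path, "gps_panel")) panel_path
           else read_panel(panel_path, weights = weights)
  if (format_hint == "auto")
    format_hint <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) "vcf" else "tsv"
  g <- if (format_hint == "vcf") read_genotypes_vcf(genotype_path, panel)
       else read_genotypes_tsv(genotype_path)
  shared_snps <- intersect(panel$snp_id, colnames(g))
  if (!length(shared_snps))
    stop("panel and genotype file share no SNPs")
  g <- g[, shared_snps, drop = FALSE]
  ph <- read_phenotypes(phenotype_path)
  shared <- intersect(rownames(g), ph$individual_id)
  if (!length(shared)) stop("no individuals shared between genotype and phenotype tables")
  unmatched <- list(genotype_only = setdiff(rownames(g), shared),
                    phenotype_only = setdiff(ph$individual_id, shared))
  n_un <- lengths(unmatched)
  if (any(n_un > 0))
    message("dropping unmatched records: ", n_un[1], " genotype-only, ",
            n_un[2], " phenotype-only")
  list(panel = panel,
       genotypes = g[shared, , drop = FALSE],
       phenotypes = ph[match(shared, ph$individual_id), , drop = FALSE],
       unmatched = unmatched)
}
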