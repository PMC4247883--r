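# Small in-code fixtures shared across test files.

mini_panel <- function(weights = c(0.1, 0.2, 0.3)) {
  gps_panel(data.frame(
    snp_id = c("rsA", "rsB", "rsC"),
    locus = c("L1", "L2", "L3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    weight = weights,
    ref_eaf = c(0.30, 0.50, 0.20),
    eaf = c(0.30, 0.50, 0.20)), name = "mini")
}

# effect-allele counts for individuals i1..i4 at rsA/rsB/rsC
mini_genotypes <- function() {
  matrix(c(0L, 1L, 2L, NA,
           1L, NA, 2L, 0L,
           2L, 0L, 1L, 0L),
         nrow = 4, dimnames = list(c("i1", "i2", "i3", "i4"),
                                   c("rsA", "rsB", "rsC")))
}

write_mini_genotype_tsv <- function(path) {
  writeLines(c("individual_id\trsA\trsB\trsC",
               "i1\t0\t1\t2",
               "i2\t1\tNA\t0",
               "i3\t2\t2\t1",
               "i4\tNA\t0\t0"), path)
  path
}

# the same genotypes as a VCF; rsA and rsC have the effect allele as REF,
# rsB as ALT, to exercise both orientations
write_mini_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3\ti4",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0\t./.",
    "1\t200\trsB\tT\tC\t.\tPASS\t.\tGT\t0/1\t./.\t1/1\t0/0",
    "1\t300\trsC\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1\t1/1"), path)
  path
}

write_mini_phenotypes <- function(path) {
  writeLines(c(
    "individual_id\tage\tsex\tsmoking\tactivity\tweight\theight\twaist\thip",
    "i1\t45\tmale\tnever\tlow\t70\t1.70\t85\t95",
    "i2\t52\tfemale\tcurrent\tnone\t86.7\t1.70\t102\t108",
    "i3\t33\tfemale\tformer\thigh\t55\t1.62\t70\t90",
    "i4\t60\tmale\tnever\tmedium\t95\t1.80\t105\t110"), path)
  path
}

# expand genotype counts into a one-column matrix
counts_to_matrix <- function(n0, n1, n2, snp_id = "snp") {
  g <- rep(c(0L, 1L, 2L), c(n0, n1, n2))
  matrix(g, ncol = 1,
         dimnames = list(sprintf("s%04d", seq_along(g)), snp_id))
}

# first-principles HWE chi-square oracle, kept deliberately naive
hwe_chi2_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - f) * (1 - f)
  e1 <- n * 2 * f * (1 - f)
  e2 <- n * f * f
  (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
}

# exact HWE oracle: enumerate all heterozygote counts compatible with the
# allele counts, with probabilities from the closed-form expression
hwe_exact_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nr <- min(n1 + 2 * n0, n1 + 2 * n2)
  hets <- seq.int(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    a <- (nr - h) / 2          # rare homozygotes
    b <- n - h - a             # common homozygotes
    h * log(2) + lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[hets == n1]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

default_adjustment <- c("age", "sex", "activity", "smoking")
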