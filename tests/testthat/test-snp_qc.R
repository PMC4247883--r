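test_that("genotype counts cover non-missing calls only", {
  cts <- isor_genotype_counts()
  fto <- counts_to_matrix(278, 370, 106, "rs9939609")
  expect_identical(unname(genotype_counts(fto, "rs9939609")),
                   c(278L, 370L, 106L))
  expect_identical(unlist(cts[cts$snp_id == "rs9939609", c("n0", "n1", "n2")],
                          use.names = FALSE),
                   c(278L, 370L, 106L))
  g <- mini_genotypes()
  g[, "rsA"] <- NA
  expect_identical(unname(genotype_counts(g, "rsA")), c(0L, 0L, 0L))
  one <- matrix(2L, 1, 1, dimnames = list("i1", "rsX"))
  expect_identical(unname(genotype_counts(one, "rsX")), c(0L, 0L, 1L))
  expect_error(genotype_counts(g, "rsZ"), "unknown")
})

test_that("effect-allele frequency matches the published two-decimal values", {
  expect_equal(round(effect_allele_frequency(c(278, 370, 106)), 2), 0.39)
  expect_equal(round(effect_allele_frequency(c(454, 267, 31)), 2), 0.22)
  expect_equal(effect_allele_frequency(c(100, 0, 0)), 0)
  expect_error(effect_allele_frequency(c(0, 0, 0)), "zero calls")
})

test_that("EAF equals half the mean coded genotype on random matrices", {
  set.seed(7)
  for (rep in 1:20) {
    f <- runif(1, 0.05, 0.95)
    g <- matrix(rbinom(300, 2, f), ncol = 1, dimnames = list(NULL, "s"))
    expect_equal(effect_allele_frequency(genotype_counts(g, "s")),
                 mean(g) / 2, tolerance = 1e-12)
  }
})

test_that("HWE chi-square reproduces the published p-values and the hand-derived statistic", {
  fto <- hwe_test(c(278, 370, 106))
  expect_equal(round(fto$p, 2), 0.33)
  expect_equal(fto$chi2, 0.94, tolerance = 0.005)
  mc4r <- hwe_test(c(454, 267, 31))
  expect_equal(round(mc4r$p, 2), 0.29)
  # counts exactly at HWE proportions
  exact <- hwe_test(c(36, 48, 16))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)
  # monomorphic column is defined, not an error
  mono <- hwe_test(c(50, 0, 0))
  expect_equal(mono$p, 1)
  expect_error(hwe_test(c(-1, 2, 3)), "non-negative")
})

test_that("HWE chi-square agrees with the first-principles oracle on random triples", {
  set.seed(11)
  for (i in 1:1000) {
    cts <- rmultinom(1, sample(50:2000, 1), prob = runif(3, 0.05, 1))[, 1]
    if (sum(cts[2:3]) == 0 || sum(cts[1:2]) == 0) next  # monomorphic
    expect_equal(hwe_test(cts)$chi2,
                 hwe_chi2_oracle(cts[1], cts[2], cts[3]),
                 tolerance = 1e-10)
  }
})

test_that("HWE p-values are uniform under the null", {
  set.seed(13)
  f <- 0.3; n <- 500
  probs <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  p <- replicate(2000, hwe_test(rmultinom(1, n, probs)[, 1])$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("the exact HWE test matches an enumeration oracle", {
  set.seed(17)
  for (i in 1:200) {
    cts <- rmultinom(1, sample(20:500, 1), prob = runif(3, 0.05, 1))[, 1]
    if (sum(cts[2:3]) == 0 || sum(cts[1:2]) == 0) next
    expect_equal(hwe_test(cts, method = "exact")$p,
                 hwe_exact_oracle(cts[1], cts[2], cts[3]),
                 tolerance = 1e-8)
  }
})

test_that("call-rate filtering keeps the 95% boundary and drops low-success SNPs", {
  set.seed(19)
  n <- 100
  g <- cbind(rsA = rbinom(n, 2, 0.3), rsB = rbinom(n, 2, 0.5),
             rsC = rbinom(n, 2, 0.2))
  rownames(g) <- sprintf("i%03d", 1:n)
  g[1:25, "rsA"] <- NA   # 75% call rate, like the excluded FANCL SNP
  g[1:5, "rsB"] <- NA    # exactly 95%
  storage.mode(g) <- "integer"
  res <- call_rate_filter(g, mini_panel(), min_rate = 0.95)
  expect_setequal(res$kept, c("rsB", "rsC"))
  expect_identical(res$dropped, "rsA")
  expect_equal(unname(res$rates["rsA"]), 0.75)
})

test_that("allele-distribution comparison flags large frequency differences and is null at equality", {
  # cohort frequency 0.15 vs reference 0.40 (the SH2B1 case)
  res <- compare_allele_distribution(c(547, 186, 17), 0.40)
  expect_lt(res$p, bonferroni_threshold(0.05, 29))
  expect_equal(compare_allele_distribution(c(25, 50, 25), 0.5)$chi2, 0)
  expect_equal(compare_allele_distribution(c(25, 50, 25), 0.5)$p, 1)
  expect_error(compare_allele_distribution(c(10, 10, 10), 1), "strictly inside")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_threshold(0.05, 29), 4), 0.0017)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
})

test_that("the QC report covers every panel SNP with consistent flags", {
  set.seed(23)
  cfg <- simulation_config(n = 400, panel = mini_panel(), missing_rate = 0.02,
                           seed = 23)
  g <- apply_missingness(simulate_genotypes(mini_panel(), 400), 0.02)
  rep <- qc_report(g, mini_panel())
  expect_identical(rep$snp_id, mini_panel()$snp_id)
  thr <- attr(rep, "threshold")
  expect_equal(thr, 0.05 / sum(rep$kept))
  expect_identical(rep$hwe_flag, rep$hwe_p <= thr)
  expect_true(all(rep$n0 + rep$n1 + rep$n2 == rep$n))
})
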