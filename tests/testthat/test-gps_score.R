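test_that("mean allele dosage equals the mean coded genotype and 2 x EAF", {
  fto <- counts_to_matrix(278, 370, 106, "rs9939609")
  expect_equal(mean_allele_count(fto, "rs9939609"), 582 / 754)
  all2 <- matrix(2L, 10, 1, dimnames = list(NULL, "s"))
  expect_equal(mean_allele_count(all2, "s"), 2)
  bal <- counts_to_matrix(7, 0, 7, "s")
  expect_equal(mean_allele_count(bal, "s"), 1)
  expect_equal(mean_allele_count(fto, "rs9939609"),
               2 * effect_allele_frequency(genotype_counts(fto, "rs9939609")))
  empty <- matrix(NA_integer_, 5, 1, dimnames = list(NULL, "s"))
  expect_error(mean_allele_count(empty, "s"), "all calls missing")
})

test_that("individuals are excluded only above the missingness tolerance", {
  g <- matrix(0L, 3, 5, dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  g["a", 1:4] <- NA  # 4 missing -> excluded
  g["b", 1:3] <- NA  # exactly 3 -> kept
  res <- exclude_high_missing(g, max_missing = 3)
  expect_identical(res$excluded, "a")
  expect_setequal(res$kept, c("b", "c"))
  expect_identical(unname(res$n_missing), c(4, 3, 0))
})

test_that("the weighted raw score sums weight times dosage with imputation", {
  p <- mini_panel(c(0.1, 0.2, 0.3))
  expect_equal(weighted_score(c(rsA = 1, rsB = 2, rsC = 0), p), 0.5)
  expect_equal(weighted_score(c(rsA = 2, rsB = 2, rsC = 2), p),
               2 * panel_weight_sum(p))
  expect_equal(weighted_score(c(rsA = 1, rsB = NA, rsC = 0), p,
                              imputation_means = c(rsB = 0.8)),
               0.26)
  expect_error(weighted_score(c(rsA = 1, rsB = NA, rsC = 0), p),
               "imputation mean")
})

test_that("rescaling maps the score to allele units on any panel", {
  set.seed(31)
  w29 <- runif(29, 0.01, 0.5)
  p29 <- gps_panel(data.frame(
    snp_id = sprintf("rs%02d", 1:29),
    effect_allele = "A", other_allele = "G", weight = w29))
  expect_equal(rescale_score(2 * sum(w29), p29), 58)
  expect_equal(rescale_score(0, p29), 0)
  p3 <- mini_panel(c(0.1, 0.2, 0.3))
  expect_equal(rescale_score(0.5, set_panel_weights(p3, c(0.2, 0.2, 0.2))),
               0.5 / 1.2 * 6)
})

test_that("the rescaled score is invariant to rescaling all weights", {
  set.seed(37)
  for (rep in 1:10) {
    m <- sample(5:20, 1)
    w <- runif(m, 0.01, 0.6)
    p1 <- gps_panel(data.frame(snp_id = sprintf("rs%d", 1:m),
                               effect_allele = "A", other_allele = "G",
                               weight = w))
    k <- runif(1, 0.1, 10)
    p2 <- set_panel_weights(p1, w * k)
    g <- matrix(rbinom(30 * m, 2, 0.4), 30, m,
                dimnames = list(sprintf("i%d", 1:30), p1$snp_id))
    g[sample(length(g), 10)] <- NA
    expect_equal(compute_gps(g, p1)$gps, compute_gps(g, p2)$gps,
                 tolerance = 1e-12)
  }
})

test_that("equal weights reduce the score to the plain risk-allele count", {
  set.seed(41)
  m <- 12
  p <- gps_panel(data.frame(snp_id = sprintf("rs%d", 1:m),
                            effect_allele = "A", other_allele = "G",
                            weight = rep(0.2, m)))
  g <- matrix(rbinom(50 * m, 2, 0.3), 50, m,
              dimnames = list(sprintf("i%d", 1:50), p$snp_id))
  expect_equal(compute_gps(g, p)$gps, rowSums(g), ignore_attr = TRUE)
})

test_that("scores always lie in [0, 2m] and excluded individuals carry NA", {
  set.seed(43)
  p <- isor_panel(synthetic_weights = TRUE)
  g <- apply_missingness(simulate_genotypes(p, 300), 0.12)
  sc <- compute_gps(g, p)
  expect_true(all(is.na(sc$gps) | (sc$gps >= 0 & sc$gps <= 58)))
  expect_identical(is.na(sc$gps), sc$excluded)
  expect_identical(sc$excluded, sc$n_missing > 3)
  expect_gt(sum(sc$excluded), 0)  # 12% missingness over 29 SNPs must exclude some
})

test_that("mean-dosage imputation leaves the population mean score unchanged", {
  set.seed(47)
  p <- isor_panel(synthetic_weights = TRUE)
  diffs <- replicate(20, {
    g <- simulate_genotypes(p, 1500)
    full <- compute_gps(g, p)$gps
    miss <- compute_gps(apply_missingness(g, 0.10), p, max_missing = 29)$gps
    mean(miss) - mean(full)
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("quartile assignment uses half-open intervals with ties going up", {
  qa <- assign_quartiles(1:8)
  expect_identical(qa$quartile, rep(1:4, each = 2L))
  # cut points of 1..9 fall on observed values 3, 5, 7: each goes up
  qa9 <- assign_quartiles(1:9)
  expect_equal(qa9$cut_points, c(3, 5, 7))
  expect_identical(qa9$quartile, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_error(assign_quartiles(c(1, 1, 1, 2)), "distinct")
})

test_that("quartiles of a large normal sample are balanced", {
  set.seed(53)
  x <- rnorm(10000, 25.7, 3.7)
  qa <- assign_quartiles(x)
  shares <- tabulate(qa$quartile, 4) / length(x)
  expect_true(all(abs(shares - 0.25) <= 0.01))
})

test_that("imputation means can be computed before or after individual exclusion", {
  set.seed(59)
  p <- mini_panel()
  g <- apply_missingness(simulate_genotypes(p, 200), 0.3)
  a <- compute_gps(g, p, max_missing = 1)
  b <- compute_gps(g, p, max_missing = 1, impute_after_exclusion = TRUE)
  expect_identical(a$excluded, b$excluded)
  expect_false(isTRUE(all.equal(attr(a, "imputation_means"),
                                attr(b, "imputation_means"))))
})
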