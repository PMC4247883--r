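test_that("a noiseless linear relation is recovered exactly", {
  x <- seq(0, 10, length.out = 50)
  res <- suppressWarnings(fit_linear(2 * x, x))  # perfect-fit summary warning
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_equal(unname(res$r2_percent[["crude"]]), 100, tolerance = 1e-8)
  expect_lte(res$lcl, res$beta); expect_gte(res$ucl, res$beta)
})

test_that("the unadjusted slope matches the closed form cov(x,y)/var(x)", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(30:300, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- fit_linear(y, x)
    expect_equal(res$beta, cov(x, y) / var(x), tolerance = 1e-10)
  }
})

test_that("linear type-I error is nominal at alpha = 0.05", {
  set.seed(67)
  hits <- replicate(1000, {
    x <- rnorm(500); y <- rnorm(500)
    fit_linear(y, x)$p < 0.05
  })
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})

test_that("collinear designs raise a singular-design error naming the column", {
  x <- rnorm(100)
  cov <- data.frame(age = x * 2)  # perfectly collinear with the exposure
  expect_error(fit_linear(rnorm(100), x, cov, "age"), "singular.*age")
})

test_that("the crude logistic OR reproduces the 2x2 cross-product", {
  # the printed quartile counts: Q1 91 controls / 33 cases, Q4 71 / 52
  y <- c(rep(0, 91), rep(1, 33), rep(0, 71), rep(1, 52))
  x <- c(rep(0, 124), rep(1, 123))
  res <- fit_logistic(y, x)
  expect_equal(res$or_value, (52 * 91) / (33 * 71), tolerance = 1e-6)
  expect_equal(round(res$or_value, 2), 2.02)
})

test_that("random 2x2 tables match the cross-product odds ratio", {
  set.seed(71)
  for (rep in 1:20) {
    tab <- matrix(sample(10:90, 4, replace = TRUE), 2)
    y <- rep(c(0, 1, 0, 1), tab)
    x <- rep(c(0, 0, 1, 1), tab)
    res <- fit_logistic(y, x)
    expect_equal(res$or_value, (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2]),
                 tolerance = 1e-6)
  }
})

test_that("a null exposure gives OR near 1 and separation is a clear error", {
  set.seed(73)
  x <- rnorm(4000)
  y <- rbinom(4000, 1, 0.3)
  expect_equal(fit_logistic(y, x)$or_value, 1, tolerance = 0.1)
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- rep(c(0, 1), each = 50)   # perfectly separated
  expect_error(fit_logistic(ys, xs), "converge|separation")
})

test_that("quartile table has a unit reference OR and a calibrated trend test", {
  set.seed(79)
  n <- 2000
  gps <- rnorm(n, 25.7, 3.7)
  p <- plogis(-0.8 + 0.20 * (gps - mean(gps)))
  y <- runif(n) < p
  qt <- quartile_or_analysis(gps, y)
  expect_equal(qt$or_value[1], 1)
  expect_equal(sum(qt$n_controls + qt$n_cases), n)
  expect_true(all(diff(qt$or_value) > -1e-9))   # non-decreasing across quartiles
  expect_lt(attr(qt, "p_trend"), 0.01)
})

test_that("the trend test has approximately nominal size under the null", {
  set.seed(83)
  rej <- replicate(250, {
    gps <- rnorm(400, 25.7, 3.7)
    y <- rbinom(400, 1, 0.35)
    attr(quartile_or_analysis(gps, y), "p_trend") < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("explained-variance decomposition behaves at the extremes", {
  set.seed(89)
  gps <- rnorm(300, 25, 3)
  dec <- suppressWarnings(explained_variance_decomposition(gps, gps))
  expect_equal(dec$r2_crude, 100, tolerance = 1e-8)
  expect_equal(dec$r2_full, 100, tolerance = 1e-8)
  expect_equal(dec$r2_covariables, 0, tolerance = 1e-8)
  covs <- data.frame(age = rnorm(300))
  dec0 <- explained_variance_decomposition(rnorm(300), gps, covs, "age")
  expect_lt(dec0$r2_full, 3)
})

test_that("adjusted and crude estimates agree when covariates are independent", {
  set.seed(97)
  deltas <- replicate(50, {
    n <- 400
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    covs <- data.frame(age = rnorm(n))
    fit_linear(y, x, covs, "age")$beta - fit_linear(y, x)$beta
  })
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(length(deltas)))
})

test_that("direction consistency uses the exact one-sided binomial tail", {
  res <- direction_consistency(c(rep(0.1, 23), rep(-0.1, 6)))
  expect_equal(res$k_consistent, 23)
  expect_equal(res$n, 29)
  expect_equal(res$p_one_sided, 621616 / 2^29, tolerance = 1e-12)
  expect_equal(round(res$p_one_sided, 5), 0.00116)
  # all consistent: p = 2^-n
  all_pos <- direction_consistency(rep(0.2, 10))
  expect_equal(all_pos$p_one_sided, 2^-10, tolerance = 1e-12)
  # near-even split leaves most of the mass above
  even <- direction_consistency(c(rep(1, 15), rep(-1, 14)))
  expect_gt(even$p_one_sided, 0.4)
  # a beta of exactly zero counts as inconsistent
  tie <- direction_consistency(c(0, 0.5, 0.5))
  expect_equal(tie$k_consistent, 2)
})

test_that("the exact binomial tail matches a brute-force tail sum", {
  tail_oracle <- function(k, n) sum(choose(n, k:n)) / 2^n
  for (k in c(15, 20, 23, 29)) {
    expect_equal(direction_consistency(
      c(rep(1, k), rep(-1, 29 - k)))$p_one_sided,
      tail_oracle(k, 29), tolerance = 1e-12)
  }
})
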