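test_that("focus density is count per micrometre", {
  expect_equal(focusDensity(0, 10), 0)
  expect_equal(focusDensity(30, 15), 2)
  expect_equal(focusDensity(c(3, 6), c(2, 2)), c(1.5, 3))
  expect_error(focusDensity(3, 0), "positive")
  expect_error(focusDensity(-1, 5), "non-negative")
})

test_that("tripling the focus rate triples the median density", {
  base <- syntheticParams(seed = 41L, focusRatePerPx = 0.02)
  high <- syntheticParams(seed = 42L, focusRatePerPx = 0.06)
  densOf <- function(p) {
    coh <- generateCohort(p, nFragments = 400L)
    truth <- attr(coh, "groundTruth")
    vapply(seq_along(coh), function(i) {
      lenUm <- fragmentLength(coh[[i]]) * p@pixelSizeNm / 1000
      focusDensity(length(truth[[i]]$focus_positions), lenUm)
    }, 0)
  }
  ratio <- median(densOf(high)) / median(densOf(base))
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})

test_that("intensity ratio applies background correction", {
  expect_equal(intensityRatio(7, 7, 3), 1)
  expect_equal(intensityRatio(10, 4, 2), 4)
  expect_equal(intensityRatio(10, 4, 0), 2.5)  # plain ratio at bg 0
  expect_error(intensityRatio(5, 3, 3), "undefined ratio")
})

test_that("G-test matches the closed form and distribution oracle", {
  perfect <- likelihoodRatioTest(matrix(c(10, 10, 10, 10), 2))
  expect_equal(perfect$G, 0)
  expect_equal(perfect$p_value, 1)

  diag <- likelihoodRatioTest(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$G, 2 * 40 * log(2), tolerance = 1e-12)
  expect_lt(diag$p_value, 1e-12)

  tab <- matrix(c(18, 7, 11, 14), 2)
  res <- likelihoodRatioTest(tab)
  expect_equal(res$p_value, chisq1PNorm(res$G), tolerance = 1e-10)
  # G >= 0 and invariance under row/column swaps
  expect_gte(res$G, 0)
  expect_equal(likelihoodRatioTest(tab[2:1, ])$G, res$G)
  expect_equal(likelihoodRatioTest(tab[, 2:1])$G, res$G)
  expect_equal(likelihoodRatioTest(t(tab))$G, res$G)

  expect_error(likelihoodRatioTest(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(likelihoodRatioTest(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("Mann-Whitney matches the exhaustive permutation oracle", {
  # separated groups: U = 0 (first-group orientation), exact p = 0.1
  res <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mwPermutationP(c(1, 2, 3), c(10, 11, 12)))

  # identical groups: ties force the normal approximation, p near 1
  same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.9)

  # random no-tie cases agree exactly with enumeration
  set.seed(43)
  for (i in 1:5) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mannWhitney(a, b)$p_value, mwPermutationP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney approximation tracks enumeration", {
  set.seed(44)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  res <- mannWhitney(c(a, 99), c(b, 99))  # tie forces the approximation
  expect_equal(res$method, "normal_approx")
  a2 <- rnorm(9); b2 <- rnorm(9, 0.3)
  res2 <- mannWhitney(a2, b2)
  expect_equal(res2$method, "normal_approx")
  expect_lt(abs(res2$p_value - mwPermutationP(a2, b2)), 0.01)
})

test_that("Mann-Whitney p is invariant under monotone transformation", {
  set.seed(45)
  a <- runif(7, 1, 2); b <- runif(9, 1.2, 2.4)
  p1 <- mannWhitney(a, b)$p_value
  expect_equal(mannWhitney(exp(a), exp(b))$p_value, p1)
  expect_equal(mannWhitney(a^3, b^3)$p_value, p1)
  expect_error(mannWhitney(numeric(0), b), "non-empty")
})

test_that("the unpaired t-test convenience wraps the equal-variance test", {
  set.seed(46)
  a <- rnorm(4, 18); b <- rnorm(3, 16.7)
  res <- unpairedTTest(a, b)
  expect_s3_class(res, "htest")
  expect_equal(res$parameter[["df"]], 5)
})
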