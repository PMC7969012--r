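test_that("fragment scaling matches hand computation and is definitional", {
  pr <- axisProfile(cbind(a = c(1, 2, 3), b = c(2, 0, 4)))
  sf <- scaleFragment(pr, primary = "a", partner = "b")
  expect_equal(sf@s, c(-1, 0, 1))  # mean 2, sample sd 1
  set.seed(21)
  for (i in 1:5) {
    L <- sample(5:40, 1)
    pr <- axisProfile(cbind(x = rnorm(L, 100, 20), y = rnorm(L, 50, 5)))
    sf <- scaleFragment(pr, "x", "y")
    expect_lt(abs(mean(sf@s)), 1e-9)
    expect_lt(abs(sd(sf@s) - 1), 1e-9)
    expect_lt(abs(mean(sf@r)), 1e-9)
    expect_lt(abs(sd(sf@r) - 1), 1e-9)
  }
})

test_that("degenerate fragments are refused and counted", {
  const <- axisProfile(cbind(a = c(4, 4, 4), b = c(1, 2, 3)))
  expect_error(scaleFragment(const, "a", "b"), "degenerate")
  ok <- axisProfile(cbind(a = c(1, 5, 3), b = c(1, 2, 3)))
  expect_warning(sc <- scaleCohort(list(const, ok), "a", "b"),
                 "excluded 1 degenerate")
  expect_length(sc, 1)
})

test_that("lag products enumerate the admissible pairs", {
  sf <- makeScaled(c(1, 2, 3), c(3, 2, 1))  # s = (-1,0,1), r = (1,0,-1)
  auto <- lagProducts(sf, "auto", 2)
  expect_equal(auto@products[[2]], c(0, 0))   # lag 1
  expect_equal(auto@products[[3]], -1)        # lag 2
  cross <- lagProducts(sf, "cross", 2)
  expect_equal(cross@products[[1]], c(-1, 0, -1))  # lag 0
  # lag 1 has both orientations: s1 r2, s2 r3, s2 r1, s3 r2
  expect_equal(sort(cross@products[[2]]), sort(c(0, 0, 0, 0)))
  # cross with r = s collapses to the auto products at lag 0
  sfEq <- makeScaled(c(1, 5, 2, 4), c(1, 5, 2, 4))
  expect_equal(lagProducts(sfEq, "cross", 0)@products[[1]],
               lagProducts(sfEq, "auto", 0)@products[[1]])
  # a fragment shorter than x + 1 contributes nothing at that lag
  expect_length(lagProducts(sf, "auto", 5)@products[[6]], 0)
})

test_that("curve values match hand computation on one fragment", {
  sf <- makeScaled(c(1, 2, 3), c(1, 2, 3))
  cv <- correlationCurve(list(sf), "auto", 2)
  expect_equal(cv@values, c(2 / 3, 0, -1))
  # averaging is idempotent: two identical fragments give the same curve
  cv2 <- correlationCurve(list(sf, sf), "auto", 2)
  expect_equal(cv2@values, cv@values)
})

test_that("g flips sign with a sign-flipped partner and is symmetric in (s, r)", {
  set.seed(22)
  frags <- randomScaledFragments(6)
  flipped <- lapply(frags, function(f) {
    new("ScaledFragment", s = f@s, r = -f@r, cellId = f@cellId,
        fragmentId = f@fragmentId, condition = f@condition)
  })
  swapped <- lapply(frags, function(f) {
    new("ScaledFragment", s = f@r, r = f@s, cellId = f@cellId,
        fragmentId = f@fragmentId, condition = f@condition)
  })
  g <- correlationCurve(frags, "cross", 8)@values
  expect_equal(correlationCurve(flipped, "cross", 8)@values, -g)
  expect_equal(correlationCurve(swapped, "cross", 8)@values, g)
})

test_that("curves match the brute-force all-pairs oracle to 1e-12", {
  set.seed(23)
  for (rep in 1:4) {
    frags <- randomScaledFragments(sample(1:5, 1), c(5L, 12L))
    plain <- lapply(frags, function(f) list(s = f@s, r = f@r))
    for (mode in c("auto", "cross")) {
      for (est in c("fragment_mean", "pooled")) {
        got <- correlationCurve(frags, mode, 4, estimator = est)@values
        want <- bruteCurve(plain, mode, 4, est)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("auto curve at lag 0 equals the mean of (L-1)/L exactly", {
  set.seed(24)
  for (rep in 1:5) {
    frags <- randomScaledFragments(sample(2:10, 1), c(3L, 30L))
    cv <- correlationCurve(frags, "auto", 0)
    want <- mean(vapply(frags, function(f) {
      L <- length(f@s); (L - 1) / L
    }, 0))
    expect_equal(cv@values[1], want, tolerance = 1e-12)
  }
})

test_that("pooled per-fragment autocorrelation agrees with stats::acf", {
  # independent route: R's acf normalizes by sum(s^2) = L - 1, ours by
  # the per-lag pair count L - x
  set.seed(25)
  s <- zScale(rnorm(40))
  sf <- makeScaled(s, rnorm(40)); sf@s <- s  # keep exact series
  cv <- correlationCurve(list(sf), "auto", 10)
  ac <- stats::acf(s, lag.max = 10, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  L <- length(s)
  expect_equal(cv@values, ac * (L - 1) / (L - 0:10), tolerance = 1e-10)
})

test_that("per-lag t-tests match an independent distribution oracle", {
  lp <- new("LagProducts", lags = 0L, products = list(c(1, -1, 1, -1)),
            fragmentIndex = list(rep(1L, 4)), mode = "cross")
  res <- lagTtest(lp)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  lpDeg <- new("LagProducts", lags = 0L, products = list(c(1, 1, 1, 1)),
               fragmentIndex = list(rep(1L, 4)), mode = "cross")
  resDeg <- lagTtest(lpDeg)
  expect_equal(resDeg$p_value, 0)
  expect_true(resDeg$degenerate)

  x <- c(0.5, 0.1, 0.3, 0.7, 0.4)
  lpX <- new("LagProducts", lags = 0L, products = list(x),
             fragmentIndex = list(rep(1L, 5)), mode = "cross")
  expect_equal(lagTtest(lpX)$p_value, tTestPBeta(x), tolerance = 1e-10)

  lp1 <- new("LagProducts", lags = 0L, products = list(1),
             fragmentIndex = list(1L), mode = "cross")
  expect_true(is.na(lagTtest(lp1)$p_value))  # < 2 samples: undefined
})

test_that("curve p-values agree between the two sample units and routes", {
  set.seed(26)
  frags <- randomScaledFragments(8, c(10L, 20L))
  pooledProducts <- poolLagProducts(frags, "cross", 5)
  for (unit in c("product", "fragment_mean")) {
    cv <- correlationCurve(frags, "cross", 5, sampleUnit = unit)
    tt <- lagTtest(pooledProducts, sampleUnit = unit)
    expect_equal(cv@pValues, tt$p_value, tolerance = 1e-10)
  }
})

test_that("curve errors on lags with no contributing fragment", {
  frags <- list(makeScaled(rnorm(5), rnorm(5)))
  expect_error(correlationCurve(frags, "auto", 10), "lag")
})

test_that("condition comparison: self-difference is zero, lags intersect", {
  set.seed(27)
  fragsA <- randomScaledFragments(10, c(10L, 20L))
  cvA <- correlationCurve(fragsA, "cross", 8)
  self <- compareConditions(cvA, cvA)
  expect_equal(self$difference, rep(0, 9))
  expect_true(all(self$p_value == 1))

  fragsB <- randomScaledFragments(10, c(12L, 20L))
  cvB <- correlationCurve(fragsB, "cross", 6)
  cmp <- compareConditions(cvA, cvB)
  expect_equal(cmp$lag_px, 0:6)
  expect_true(all(c("p_bonferroni", "p_bh") %in% names(cmp)))
})

test_that("depleted and non-depleted cohorts differ at lag 0", {
  pDep <- syntheticParams(depletionDepth = 0.8, seed = 301L)
  pNull <- syntheticParams(depletionDepth = 0, seed = 302L)
  cohD <- generateCohort(pDep, nFragments = 300L)
  cohN <- generateCohort(pNull, nFragments = 300L)
  cvD <- correlationCurve(scaleCohort(cohD, "platform", "focus"), "cross", 10)
  cvN <- correlationCurve(scaleCohort(cohN, "platform", "focus"), "cross", 10)
  cmp <- compareConditions(cvD, cvN)
  expect_lt(cmp$difference[1], 0)
  expect_lt(cmp$p_bh[1], 0.05)
})

test_that("firstPositiveLag reads off the crossing lag", {
  v <- c(-0.2, -0.1, -0.05, 0.01, 0.03)
  expect_equal(firstPositiveLag(v), 3L)
  expect_true(is.na(firstPositiveLag(c(-1, -0.5, -0.1))))
})
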