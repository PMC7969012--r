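# Independent oracles used across the suite. These deliberately use
# different computational routes than the package (explicit double loops,
# enumeration, special-function identities) so agreement is evidence, not
# tautology.

# All-pairs double-loop correlation curve on plain list(s=, r=) fragments.
bruteCurve <- function(frags, mode, xMax,
                       estimator = c("fragment_mean", "pooled")) {
  estimator <- match.arg(estimator)
  nf <- length(frags)
  perFragMean <- matrix(NA_real_, nf, xMax + 1)
  pooled <- vector("list", xMax + 1)
  for (f in seq_len(nf)) {
    s <- frags[[f]]$s
    r <- if (mode == "auto") s else frags[[f]]$r
    L <- length(s)
    for (x in 0:xMax) {
      prods <- c()
      for (i in seq_len(L)) for (j in seq_len(L)) {
        if (mode == "auto") {
          if (j - i == x) prods <- c(prods, s[i] * s[j])
        } else {
          if (abs(i - j) == x) prods <- c(prods, s[i] * r[j])
        }
      }
      if (length(prods)) {
        perFragMean[f, x + 1] <- mean(prods)
        pooled[[x + 1]] <- c(pooled[[x + 1]], prods)
      }
    }
  }
  if (estimator == "fragment_mean") colMeans(perFragMean, na.rm = TRUE)
  else vapply(pooled, mean, 0)
}

# Two-sided one-sample t-test p via the incomplete-beta identity
# P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2).
tTestPBeta <- function(x) {
  n <- length(x)
  tt <- mean(x) / (sd(x) / sqrt(n))
  stats::pbeta((n - 1) / ((n - 1) + tt^2), (n - 1) / 2, 0.5)
}

# Chi-square(1) upper tail through the normal distribution.
chisq1PNorm <- function(q) 2 * stats::pnorm(sqrt(q), lower.tail = FALSE)

# Exhaustive-permutation two-sided Mann-Whitney p (midrank U statistic),
# p = 2 * min(P(U <= u), P(U >= u)) capped at 1, over all assignments.
mwPermutationP <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  uStat <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - nA * (nA + 1) / 2
  }
  uObs <- uStat(seq_len(nA))
  combos <- utils::combn(length(pooled), nA)
  us <- apply(combos, 2, uStat)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Plain-vector z-scaling for building ScaledFragment fixtures.
zScale <- function(v) (v - mean(v)) / sd(v)

makeScaled <- function(s, r = NULL, id = "f", cell = "c") {
  if (is.null(r)) r <- rev(s)  # arbitrary partner when unused
  new("ScaledFragment", s = zScale(s), r = zScale(r),
      cellId = cell, fragmentId = id, condition = "test")
}

# Random already-scaled fragment list for property tests.
randomScaledFragments <- function(n, lenRange = c(5L, 12L)) {
  lapply(seq_len(n), function(i) {
    L <- sample(lenRange[1]:lenRange[2], 1)
    makeScaled(rnorm(L), rnorm(L), id = paste0("f", i))
  })
}

# g(0) of one synthetic cohort run through the public API.
cohortG0 <- function(params, nFragments = 500L, seed = 1L,
                     sampleUnit = "fragment_mean", xMax = 0L) {
  params@seed <- as.integer(seed)
  coh <- generateCohort(params, nFragments = nFragments)
  sc <- suppressWarnings(scaleCohort(coh, "platform", "focus"))
  cv <- correlationCurve(sc, "cross", xMax = xMax, sampleUnit = sampleUnit)
  list(g0 = cv@values[1], p0 = cv@pValues[1], curve = cv)
}
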