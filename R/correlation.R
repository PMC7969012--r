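#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn scaleFragment z-scale the primary/partner channel pair.
#'
#' Each channel is centered by its fragment mean and divided by its
#' sample standard deviation (divisor L - 1), giving the series `s`
#' (primary, e.g. IHO1) and `r` (partner, e.g. DMC1/RAD51) used by
#' [correlationCurve()]. A consequence of the sample-sd convention is
#' that the auto-correlation at lag 0 is exactly (L - 1) / L for a
#' fragment of length L.
#'
#' @param primary,partner channel names in the profile.
#' @export
setMethod("scaleFragment", "AxisProfile",
  function(profile, primary, partner, ...) {
    m <- profile@intensities
    for (nm in c(primary, partner)) if (!nm %in% colnames(m))
      stop("channel '", nm, "' not present in profile ",
           profile@fragmentId, " (has: ",
           paste(colnames(m), collapse = ", "), ")")
    if (nrow(m) < 3L)
      stop("degenerate fragment ", profile@fragmentId,
           ": length must be >= 3")
    z <- function(v) {
      sdv <- stats::sd(v)
      if (!is.finite(sdv) || sdv == 0)
        stop("degenerate fragment ", profile@fragmentId,
             ": zero-variance channel")
      (v - mean(v)) / sdv
    }
    new("ScaledFragment", s = z(m[, primary]), r = z(m[, partner]),
        cellId = profile@cellId, fragmentId = profile@fragmentId,
        condition = profile@condition)
  })

## Per-fragment, per-lag product statistics (sum, sum of squares, count).
## Auto mode uses one orientation (i, i + x); cross mode pools both
## orientations for x > 0 because the lag x = |i - j| is unsigned.
.fragLagStats <- function(s, r, mode, xMax) {
  L <- length(s)
  lags <- 0:xMax
  n <- sum1 <- sum2 <- numeric(xMax + 1)
  for (x in lags) {
    if (L - x < 1L || L < 2L) next  # too short: contributes nothing
    a <- seq_len(L - x)
    if (mode == "auto") {
      p <- s[a] * s[a + x]
    } else if (x == 0L) {
      p <- s * r
    } else {
      p <- c(s[a] * r[a + x], s[a + x] * r[a])
    }
    n[x + 1] <- length(p)
    sum1[x + 1] <- sum(p)
    sum2[x + 1] <- sum(p * p)
  }
  list(n = n, sum1 = sum1, sum2 = sum2)
}

#' @describeIn lagProducts enumerate the products for one fragment.
#'
#' @param mode `"auto"` (s against s) or `"cross"` (s against r).
#' @param xMax maximum lag in pixels; lags with no admissible pair in
#'   the fragment get an empty product vector.
#' @export
setMethod("lagProducts", "ScaledFragment",
  function(frag, mode = c("cross", "auto"), xMax = 20L, ...) {
    mode <- match.arg(mode)
    xMax <- as.integer(xMax)
    stopifnot(xMax >= 0L)
    s <- frag@s; r <- frag@r; L <- length(s)
    prods <- vector("list", xMax + 1)
    for (x in 0:xMax) {
      if (L - x < 1L) { prods[[x + 1]] <- numeric(0); next }
      a <- seq_len(L - x)
      prods[[x + 1]] <- if (mode == "auto") s[a] * s[a + x]
        else if (x == 0L) s * r
        else c(s[a] * r[a + x], s[a + x] * r[a])
    }
    new("LagProducts", lags = 0:xMax, products = prods,
        fragmentIndex = lapply(prods, function(p) rep(1L, length(p))),
        mode = mode)
  })

#' Pool lag products across several fragments
#'
#' @param frags list of [ScaledFragment-class].
#' @param mode,xMax see [lagProducts()].
#' @return a [LagProducts-class] with `fragmentIndex` tagging the source
#'   fragment of every product.
#' @export
poolLagProducts <- function(frags, mode = c("cross", "auto"), xMax = 20L) {
  mode <- match.arg(mode)
  per <- lapply(frags, lagProducts, mode = mode, xMax = xMax)
  prods <- lapply(seq_len(xMax + 1), function(k)
    unlist(lapply(per, function(lp) lp@products[[k]]), use.names = FALSE))
  idx <- lapply(seq_len(xMax + 1), function(k)
    unlist(lapply(seq_along(per), function(f)
      rep(f, length(per[[f]]@products[[k]]))), use.names = FALSE))
  new("LagProducts", lags = 0:as.integer(xMax), products = prods,
      fragmentIndex = idx, mode = mode)
}

#' Averaged auto-/cross-correlation curve over fragments
#'
#' Computes c(x) (auto) or g(x) (cross) for lags x = 0..`xMax` from a
#' cohort of scaled fragments. With the default `estimator =
#' "fragment_mean"`, the mean product at each lag is computed within
#' each fragment first and these per-fragment means are averaged with
#' equal weight over all fragments from all cells of a condition; the
#' `"pooled"` estimator instead averages all products of a lag directly
#' (which weights fragments by their number of admissible pairs, as
#' classical correlogram estimators do).
#'
#' Fragments shorter than x + 1 contribute no products at lag x; a lag
#' at which no fragment contributes is an error (reduce `xMax`).
#'
#' Per-lag two-sided one-sample t-tests of the products against 0 test
#' the null hypothesis that the scaled signals are uncorrelated at that
#' axial distance. With `sampleUnit = "product"` each individual product
#' is a sample (products within a fragment are not independent, so
#' these p-values are optimistic at large counts); with `sampleUnit =
#' "fragment_mean"` the per-fragment means are the samples, which
#' respects the independence structure of the cohort.
#'
#' @param fragments list of [ScaledFragment-class] (zero-variance
#'   fragments must have been excluded upstream; [scaleFragment()]
#'   refuses to create them).
#' @param mode `"cross"` for g(x) (default) or `"auto"` for c(x).
#' @param xMax maximum lag in pixels (default 20).
#' @param estimator `"fragment_mean"` (default) or `"pooled"`.
#' @param sampleUnit t-test sample unit, `"product"` (default) or
#'   `"fragment_mean"`.
#' @param pixelSizeNm pixel size for the distance axis (default 65).
#' @return a [CorrelationCurve-class].
#' @seealso [lagTtest()], [compareConditions()]
#' @export
correlationCurve <- function(fragments, mode = c("cross", "auto"),
                             xMax = 20L,
                             estimator = c("fragment_mean", "pooled"),
                             sampleUnit = c("product", "fragment_mean"),
                             pixelSizeNm = 65) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  sampleUnit <- match.arg(sampleUnit)
  xMax <- as.integer(xMax)
  stopifnot(xMax >= 0L, length(fragments) >= 1L)
  nf <- length(fragments)
  nLag <- xMax + 1L
  n <- s1 <- s2 <- matrix(0, nf, nLag)
  for (f in seq_len(nf)) {
    fr <- fragments[[f]]
    st <- .fragLagStats(fr@s, if (mode == "auto") fr@s else fr@r,
                        mode, xMax)
    n[f, ] <- st$n; s1[f, ] <- st$sum1; s2[f, ] <- st$sum2
  }
  contrib <- n > 0
  nContrib <- colSums(contrib)
  if (any(nContrib == 0))
    stop("no fragment contributes products at lag(s) ",
         paste(which(nContrib == 0) - 1L, collapse = ", "),
         "; reduce xMax")
  fragMean <- s1 / ifelse(contrib, n, NA)  # NA where no contribution
  ## curve value per estimator
  values <- if (estimator == "fragment_mean")
    colMeans(fragMean, na.rm = TRUE)
  else colSums(s1) / colSums(n)
  ## t-test samples per sampleUnit
  if (sampleUnit == "fragment_mean") {
    unitN <- nContrib
    unitMean <- colMeans(fragMean, na.rm = TRUE)
    unitVar <- apply(fragMean, 2, stats::var, na.rm = TRUE)
  } else {
    unitN <- colSums(n)
    unitMean <- colSums(s1) / unitN
    unitVar <- (colSums(s2) - unitN * unitMean^2) / (unitN - 1)
  }
  unitVar <- pmax(unitVar, 0)
  sem <- sqrt(unitVar / unitN)
  degenerate <- unitN >= 2 & unitVar == 0
  tstat <- unitMean / sem
  p <- 2 * stats::pt(abs(tstat), df = unitN - 1, lower.tail = FALSE)
  p[degenerate & unitMean != 0] <- 0
  p[degenerate & unitMean == 0] <- 1
  p[unitN < 2] <- NA_real_
  cells <- unique(vapply(fragments, function(fr) fr@cellId, ""))
  new("CorrelationCurve", lags = 0:xMax, values = as.numeric(values),
      sem = as.numeric(sem), nProducts = as.integer(colSums(n)),
      nSamples = as.integer(unitN), unitMean = as.numeric(unitMean),
      unitVar = as.numeric(unitVar), pValues = as.numeric(p),
      degenerate = as.logical(degenerate), kind = mode,
      estimator = estimator, sampleUnit = sampleUnit,
      nFragments = as.integer(nf), nCells = length(cells),
      pixelSizeNm = pixelSizeNm)
}

#' Per-lag one-sample t-test of pooled lag products against zero
#'
#' Two-sided one-sample t-test of the products at each lag against a
#' mean of 0 (the null hypothesis that the scaled signals are
#' uncorrelated at that distance), with p from the t distribution on
#' n - 1 degrees of freedom. `sampleUnit = "product"` treats every
#' product as a sample; `"fragment_mean"` first averages within
#' fragments. A zero-variance sample with nonzero mean is reported as
#' p = 0 with `degenerate = TRUE`.
#'
#' @param products a [LagProducts-class] (see [poolLagProducts()]).
#' @param sampleUnit `"product"` (default) or `"fragment_mean"`.
#' @return data.frame with columns `lag_px`, `n`, `mean`, `t`,
#'   `p_value`, `degenerate`.
#' @export
lagTtest <- function(products, sampleUnit = c("product", "fragment_mean")) {
  sampleUnit <- match.arg(sampleUnit)
  res <- lapply(seq_along(products@lags), function(k) {
    p <- products@products[[k]]
    if (sampleUnit == "fragment_mean") {
      idx <- products@fragmentIndex[[k]]
      p <- as.numeric(tapply(p, idx, mean))
    }
    nk <- length(p)
    if (nk < 2L)
      return(data.frame(lag_px = products@lags[k], n = nk,
                        mean = if (nk) mean(p) else NA_real_,
                        t = NA_real_, p_value = NA_real_,
                        degenerate = FALSE))
    m <- mean(p); v <- stats::var(p)
    if (v == 0) {
      return(data.frame(lag_px = products@lags[k], n = nk, mean = m,
                        t = if (m == 0) 0 else Inf * sign(m),
                        p_value = if (m == 0) 1 else 0,
                        degenerate = TRUE))
    }
    tt <- m / sqrt(v / nk)
    data.frame(lag_px = products@lags[k], n = nk, mean = m, t = tt,
               p_value = 2 * stats::pt(abs(tt), df = nk - 1,
                                       lower.tail = FALSE),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Compare two correlation curves lag by lag
#'
#' Per-lag difference of curve values (A minus B) over the intersection
#' of the two lag ranges, with a Welch two-sample t-test on the per-lag
#' underlying samples (in each curve's `sampleUnit`) and
#' multiple-testing adjustment columns (Bonferroni and
#' Benjamini-Hochberg across the compared lags).
#'
#' @param curveA,curveB [CorrelationCurve-class] objects with
#'   overlapping lag ranges and the same `sampleUnit`.
#' @return data.frame with columns `lag_px`, `valueA`, `valueB`,
#'   `difference`, `t`, `df`, `p_value`, `p_bonferroni`, `p_bh`.
#' @export
compareConditions <- function(curveA, curveB) {
  stopifnot(is(curveA, "CorrelationCurve"), is(curveB, "CorrelationCurve"))
  if (curveA@sampleUnit != curveB@sampleUnit)
    stop("curves must share the same sampleUnit")
  common <- intersect(curveA@lags, curveB@lags)
  if (!length(common))
    stop("curves have disjoint lag ranges (",
         paste(range(curveA@lags), collapse = ".."), " vs ",
         paste(range(curveB@lags), collapse = ".."), ")")
  ia <- match(common, curveA@lags); ib <- match(common, curveB@lags)
  m1 <- curveA@unitMean[ia]; v1 <- curveA@unitVar[ia]; n1 <- curveA@nSamples[ia]
  m2 <- curveB@unitMean[ib]; v2 <- curveB@unitVar[ib]; n2 <- curveB@nSamples[ib]
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  data.frame(lag_px = common,
             valueA = curveA@values[ia], valueB = curveB@values[ib],
             difference = curveA@values[ia] - curveB@values[ib],
             t = tt, df = df, p_value = p,
             p_bonferroni = stats::p.adjust(p, "bonferroni"),
             p_bh = stats::p.adjust(p, "BH"))
}

#' Scale a cohort of profiles, excluding degenerate fragments
#'
#' Applies [scaleFragment()] to every profile and drops fragments that
#' are too short or have a zero-variance channel, with a warning that
#' counts the exclusions.
#'
#' @param profiles list of [AxisProfile-class].
#' @param primary,partner channel names.
#' @return list of [ScaledFragment-class].
#' @export
scaleCohort <- function(profiles, primary, partner) {
  out <- vector("list", length(profiles))
  bad <- 0L
  for (i in seq_along(profiles)) {
    out[[i]] <- tryCatch(
      scaleFragment(profiles[[i]], primary = primary, partner = partner),
      error = function(e) {
        if (!grepl("degenerate fragment", conditionMessage(e))) stop(e)
        NULL
      })
    if (is.null(out[[i]])) bad <- bad + 1L
  }
  if (bad > 0L)
    warning(sprintf("excluded %d degenerate fragment(s) of %d", bad,
                    length(profiles)))
  Filter(Negate(is.null), out)
}

#' First lag at which a curve turns positive
#'
#' Smallest lag >= `from` with a positive curve value, used to read off
#' the spatial extent of the local depletion signature (a negative
#' cross-correlation at short range crossing to positive at a distance).
#'
#' @param curve a [CorrelationCurve-class] (or numeric vector indexed
#'   from lag 0).
#' @param from first lag considered (default 1).
#' @return integer lag, or NA if the curve never turns positive.
#' @export
firstPositiveLag <- function(curve, from = 1L) {
  v <- if (is(curve, "CorrelationCurve")) curve@values else as.numeric(curve)
  lags <- if (is(curve, "CorrelationCurve")) curve@lags else
    seq_along(v) - 1L
  ok <- lags >= from & v > 0
  if (!any(ok)) return(NA_integer_)
  as.integer(lags[which(ok)[1]])
}
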