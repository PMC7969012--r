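#' @include AllClasses.R
NULL

#' Focus density per micrometre of axis
#'
#' @param count non-negative focus count(s).
#' @param axisLengthUm positive axis length(s) in micrometres.
#' @return foci per micrometre (vectorized).
#' @examples
#' focusDensity(30, 15)  # 2 foci/um
#' @export
focusDensity <- function(count, axisLengthUm) {
  if (any(!is.finite(axisLengthUm)) || any(axisLengthUm <= 0))
    stop("axis length must be positive")
  if (any(count < 0)) stop("focus count must be non-negative")
  count / axisLengthUm
}

#' Background-corrected unsynapsed/synapsed intensity ratio
#'
#' Ratio of mean signal on unsynapsed versus synapsed axis regions of a
#' partially synapsed chromosome, each corrected by the nearby nuclear
#' background: `(meanUnsynapsed - background) / (meanSynapsed -
#' background)`.
#'
#' @param meanUnsynapsed,meanSynapsed mean region intensities.
#' @param background background intensity (default 0).
#' @return the corrected ratio (vectorized).
#' @export
intensityRatio <- function(meanUnsynapsed, meanSynapsed, background = 0) {
  den <- meanSynapsed - background
  if (any(den == 0))
    stop("undefined ratio: corrected synapsed intensity is zero")
  (meanUnsynapsed - background) / den
}

#' Likelihood-ratio (G) test of independence for a 2 x 2 table
#'
#' G = 2 * sum(O * log(O / E)) over the four cells, with expected counts
#' from the margins under independence and the convention 0 * log(0) =
#' 0; p from the chi-square distribution with 1 degree of freedom. Used
#' to compare cell-category proportions (e.g. IHO1-positive versus
#' -negative spermatocytes) between two conditions.
#'
#' @param table 2 x 2 matrix of non-negative integer counts
#'   (condition x category); both margins must be positive.
#' @return list with `G`, `df`, `p_value`, and the `expected` matrix.
#' @examples
#' likelihoodRatioTest(matrix(c(20, 12, 30, 28), 2))
#' @export
likelihoodRatioTest <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("a 2 x 2 contingency table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("both margins must be positive")
  expected <- outer(rs, cs) / n
  terms <- ifelse(tab == 0, 0, tab * log(tab / expected))
  G <- 2 * sum(terms)
  G <- max(G, 0)  # guard the log round-off at perfect independence
  list(G = G, df = 1L,
       p_value = stats::pchisq(G, df = 1L, lower.tail = FALSE),
       expected = expected)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups with midrank handling
#' of ties. The reported U counts the pairs (a, b) with a > b (ties
#' counted 0.5), i.e. it is oriented on the first group. The p-value is
#' exact when `min(nA, nB) <= 8` and there are no ties, and otherwise
#' uses the normal approximation with tie and continuity correction;
#' the method used is recorded in the result.
#'
#' @param groupA,groupB non-empty numeric vectors.
#' @return list with `U`, `p_value`, `method`, `nA`, `nB`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 1L || nB < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  useExact <- min(nA, nB) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = useExact,
                       correct = TRUE, alternative = "two.sided"))
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (useExact) "exact" else "normal_approx",
       nA = nA, nB = nB)
}

#' Unpaired two-sample t-test convenience wrapper
#'
#' Plain equal-variance two-sample t-test, as used for simple cohort
#' means such as litter sizes.
#'
#' @param groupA,groupB numeric vectors.
#' @return the `htest` object from [stats::t.test()].
#' @export
unpairedTTest <- function(groupA, groupB) {
  stats::t.test(groupA, groupB, var.equal = TRUE)
}
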