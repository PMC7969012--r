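#' @import methods
NULL

.finiteNonNeg <- function(x) all(is.finite(x)) && all(x >= 0)

#' ImageChannel: one grayscale channel of a fluorescence image
#'
#' Holds a 2-D intensity grid for a single channel (e.g. the axial
#' platform protein IHO1, or a DSB-focus marker such as DMC1 or RAD51)
#' together with the physical pixel size. Intensities are in arbitrary
#' units, as is usual for immunofluorescence.
#'
#' The coordinate convention used throughout the package is (row, col),
#' 0-based, with pixel centers at integer coordinates.
#'
#' @slot pixels numeric matrix of non-negative, finite intensities.
#' @slot channelName single character label, e.g. `"IHO1"`.
#' @slot pixelSizeNm physical size of one pixel in nanometres
#'   (65 nm for the imaging setup this analysis was designed for).
#' @exportClass ImageChannel
setClass("ImageChannel",
  representation(pixels = "matrix", channelName = "character",
                 pixelSizeNm = "numeric"),
  prototype(channelName = "channel", pixelSizeNm = 65),
  validity = function(object) {
    msg <- character(0)
    if (!is.numeric(object@pixels) || nrow(object@pixels) < 1L ||
        ncol(object@pixels) < 1L)
      msg <- c(msg, "'pixels' must be a numeric matrix of dimension >= 1x1")
    else if (!.finiteNonNeg(object@pixels))
      msg <- c(msg, "all pixel intensities must be finite and >= 0")
    if (length(object@channelName) != 1L)
      msg <- c(msg, "'channelName' must be a single string")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      msg <- c(msg, "'pixelSizeNm' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' @param pixels,channelName,pixelSizeNm see slot documentation.
#' @rdname ImageChannel-class
#' @export
imageChannel <- function(pixels, channelName = "channel", pixelSizeNm = 65) {
  new("ImageChannel", pixels = as.matrix(pixels), channelName = channelName,
      pixelSizeNm = as.numeric(pixelSizeNm))
}

setMethod("show", "ImageChannel", function(object) {
  cat(sprintf("ImageChannel '%s': %d x %d px, %.3g nm/px, range [%.3g, %.3g]\n",
              object@channelName, nrow(object@pixels), ncol(object@pixels),
              object@pixelSizeNm, min(object@pixels), max(object@pixels)))
})

#' AxisTrace: a manually traced chromosome-axis segment
#'
#' An ordered polyline in image coordinates along which intensity
#' profiles are sampled, together with the sampling width. Sampling
#' averages `widthPx` perpendicular samples per arc-length step,
#' mirroring wide-line profile averaging in ImageJ (the tracing itself
#' is manual and outside the scope of this package).
#'
#' @slot vertices n x 2 numeric matrix of (row, col) coordinates,
#'   possibly fractional, 0-based.
#' @slot widthPx odd positive integer sampling width in pixels.
#' @slot cellId,fragmentId character identifiers.
#' @exportClass AxisTrace
setClass("AxisTrace",
  representation(vertices = "matrix", widthPx = "integer",
                 cellId = "character", fragmentId = "character"),
  prototype(widthPx = 5L, cellId = "cell", fragmentId = "fragment"),
  validity = function(object) {
    v <- object@vertices
    msg <- character(0)
    if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 2L)
      msg <- c(msg, "'vertices' must be a numeric matrix with >= 2 rows and 2 columns")
    else {
      if (!all(is.finite(v)))
        msg <- c(msg, "vertex coordinates must be finite")
      d <- diff(v)
      if (nrow(v) >= 2L && any(rowSums(d^2) == 0))
        msg <- c(msg, "consecutive vertices must be distinct")
    }
    if (length(object@widthPx) != 1L || is.na(object@widthPx) ||
        object@widthPx < 1L)
      msg <- c(msg, "'widthPx' must be a positive integer")
    else if (object@widthPx %% 2L == 0L)
      msg <- c(msg, "'widthPx' must be odd (the line is centered on the trace)")
    if (length(msg)) msg else TRUE
  })

#' @param vertices,widthPx,cellId,fragmentId see slot documentation.
#' @rdname AxisTrace-class
#' @export
axisTrace <- function(vertices, widthPx = 5L, cellId = "cell",
                      fragmentId = "fragment") {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  new("AxisTrace", vertices = v, widthPx = as.integer(widthPx),
      cellId = cellId, fragmentId = fragmentId)
}

setMethod("show", "AxisTrace", function(object) {
  len <- sum(sqrt(rowSums(diff(object@vertices)^2)))
  cat(sprintf("AxisTrace %s/%s: %d vertices, arc length %.2f px, width %d px\n",
              object@cellId, object@fragmentId, nrow(object@vertices),
              len, object@widthPx))
})

#' BackgroundSet: nuclear background regions for one cell
#'
#' Background fluorescence is measured per cell in a small number of
#' nuclear regions that do not overlap chromosome axes (typically 2-3).
#' Each region is either a polygon (n x 2 matrix of (row, col) vertex
#' coordinates) or a logical mask of the same dimension as the image.
#' The background estimate is the mean intensity over the union of the
#' region pixels, each pixel counted once.
#'
#' @slot regions non-empty list of polygon matrices and/or logical masks.
#' @exportClass BackgroundSet
setClass("BackgroundSet",
  representation(regions = "list"),
  validity = function(object) {
    if (length(object@regions) < 1L)
      return("at least one background region is required")
    ok <- vapply(object@regions, function(r)
      (is.matrix(r) && is.numeric(r) && ncol(r) == 2L && nrow(r) >= 3L) ||
      (is.matrix(r) && is.logical(r)), TRUE)
    if (!all(ok))
      return("each region must be an n x 2 polygon matrix (n >= 3) or a logical mask")
    TRUE
  })

#' @param regions list of regions; see slot documentation.
#' @rdname BackgroundSet-class
#' @export
backgroundSet <- function(regions) {
  if (is.matrix(regions)) regions <- list(regions)
  new("BackgroundSet", regions = regions)
}

#' AxisProfile: per-position intensities along one axis fragment
#'
#' The central container of the extraction stage: for one traced axis
#' fragment, the background-subtracted intensity of each channel at each
#' unit arc-length step (1 px ~ 65 nm of axis). Values may be negative
#' after background subtraction; they are not clipped, because the
#' downstream per-fragment scaling removes the mean anyway.
#'
#' Positions are implicit: row `k` of the intensity matrix is position
#' `k - 1` in pixels from the start of the trace (contiguous from 0).
#'
#' @slot intensities L x nChannels numeric matrix, column names are the
#'   channel names; L >= 2.
#' @slot cellId,fragmentId,condition character identifiers; `condition`
#'   is the genotype/treatment label used for cohort grouping.
#' @slot pixelSizeNm physical pixel size (nm).
#' @exportClass AxisProfile
setClass("AxisProfile",
  representation(intensities = "matrix", cellId = "character",
                 fragmentId = "character", condition = "character",
                 pixelSizeNm = "numeric"),
  prototype(cellId = "cell", fragmentId = "fragment", condition = "na",
            pixelSizeNm = 65),
  validity = function(object) {
    m <- object@intensities
    msg <- character(0)
    if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 1L)
      msg <- c(msg, "'intensities' must be a numeric matrix with >= 2 rows")
    else {
      if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "'intensities' must have unique channel column names")
      if (!all(is.finite(m)))
        msg <- c(msg, "intensities must be finite (split fragments at gaps upstream)")
    }
    if (length(msg)) msg else TRUE
  })

#' @param intensities,cellId,fragmentId,condition,pixelSizeNm see slots.
#' @rdname AxisProfile-class
#' @export
axisProfile <- function(intensities, cellId = "cell", fragmentId = "fragment",
                        condition = "na", pixelSizeNm = 65) {
  m <- as.matrix(intensities)
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, colnames(m))
  new("AxisProfile", intensities = m, cellId = cellId,
      fragmentId = fragmentId, condition = condition,
      pixelSizeNm = as.numeric(pixelSizeNm))
}

setMethod("show", "AxisProfile", function(object) {
  cat(sprintf("AxisProfile %s/%s [%s]: L = %d px, channels: %s\n",
              object@cellId, object@fragmentId, object@condition,
              nrow(object@intensities),
              paste(colnames(object@intensities), collapse = ", ")))
})

#' ScaledFragment: z-scaled signal pair for one axis fragment
#'
#' Each fragment's primary (`s`, e.g. IHO1) and partner (`r`, e.g. DMC1
#' or RAD51) series after centering to mean 0 and scaling to sample
#' standard deviation 1 (divisor L - 1). This makes fragments of
#' different brightness and length comparable before correlation.
#'
#' @slot s,r numeric vectors of equal length L >= 3, mean 0 and sample
#'   sd 1 (within 1e-9).
#' @slot cellId,fragmentId,condition character identifiers.
#' @exportClass ScaledFragment
setClass("ScaledFragment",
  representation(s = "numeric", r = "numeric", cellId = "character",
                 fragmentId = "character", condition = "character"),
  prototype(cellId = "cell", fragmentId = "fragment", condition = "na"),
  validity = function(object) {
    msg <- character(0)
    L <- length(object@s)
    if (L < 3L) msg <- c(msg, "fragment length must be >= 3")
    if (length(object@r) != L) msg <- c(msg, "'s' and 'r' must have equal length")
    tol <- 1e-9
    for (nm in c("s", "r")) {
      v <- slot(object, nm)
      if (!all(is.finite(v))) { msg <- c(msg, sprintf("'%s' must be finite", nm)); next }
      if (abs(mean(v)) > tol)
        msg <- c(msg, sprintf("'%s' must have mean 0 (|mean| = %.2g)", nm, abs(mean(v))))
      if (abs(stats::sd(v) - 1) > tol)
        msg <- c(msg, sprintf("'%s' must have sample sd 1 (sd = %.6g)", nm, stats::sd(v)))
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ScaledFragment", function(object) {
  cat(sprintf("ScaledFragment %s/%s [%s]: L = %d px\n",
              object@cellId, object@fragmentId, object@condition,
              length(object@s)))
})

#' LagProducts: pooled pairwise products per axial lag
#'
#' For each lag x, the individual products s_i * s_j (auto) or s_i * r_j
#' (cross) with |i - j| = x, pooled across fragments and tagged with the
#' fragment each product came from. Auto products use one orientation
#' (i, i + x) to avoid counting identical pairs twice; cross products at
#' x > 0 include both orientations because the lag is unsigned.
#'
#' @slot lags integer vector of lags (0..xMax).
#' @slot products list, one numeric vector of products per lag.
#' @slot fragmentIndex list, parallel to `products`: integer index of the
#'   source fragment for every product.
#' @slot mode `"auto"` or `"cross"`.
#' @exportClass LagProducts
setClass("LagProducts",
  representation(lags = "integer", products = "list",
                 fragmentIndex = "list", mode = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@products) != length(object@lags) ||
        length(object@fragmentIndex) != length(object@lags))
      msg <- c(msg, "'products' and 'fragmentIndex' must have one entry per lag")
    if (!object@mode %in% c("auto", "cross"))
      msg <- c(msg, "'mode' must be 'auto' or 'cross'")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "LagProducts", function(object) {
  cat(sprintf("LagProducts (%s): lags %d..%d, %d products total\n",
              object@mode, min(object@lags), max(object@lags),
              sum(lengths(object@products))))
})

#' CorrelationCurve: averaged correlation versus axial distance
#'
#' The result of the correlation stage: the auto-correlation c(x) of one
#' scaled signal, or the cross-correlation g(x) between two scaled
#' signals, at every axial lag x = |i - j| in pixels, averaged over
#' fragments, with per-lag dispersion, sample counts and two-sided
#' one-sample t-test p-values against 0.
#'
#' `unitMean`, `unitVar` and `nSamples` describe the per-lag samples in
#' the curve's `sampleUnit` (individual products or per-fragment means);
#' they are what the per-lag t-test and between-condition comparisons
#' are computed from.
#'
#' @slot lags integer lags in pixels (0..xMax).
#' @slot values curve value per lag (fragment-mean or pooled estimator).
#' @slot sem standard error of the mean per lag, over `sampleUnit`.
#' @slot nProducts number of pairwise products per lag.
#' @slot nSamples number of t-test samples per lag (`sampleUnit`).
#' @slot unitMean,unitVar per-lag mean and variance of the t-test samples.
#' @slot pValues two-sided per-lag p-values.
#' @slot degenerate logical per lag: TRUE where the t-test sample had
#'   zero variance (p reported as 0).
#' @slot kind `"auto"` or `"cross"`.
#' @slot estimator `"fragment_mean"` or `"pooled"`.
#' @slot sampleUnit `"product"` or `"fragment_mean"`.
#' @slot nFragments,nCells numbers of fragments and cells averaged.
#' @slot pixelSizeNm physical pixel size (nm) for the distance axis.
#' @exportClass CorrelationCurve
setClass("CorrelationCurve",
  representation(lags = "integer", values = "numeric", sem = "numeric",
                 nProducts = "integer", nSamples = "integer",
                 unitMean = "numeric", unitVar = "numeric",
                 pValues = "numeric", degenerate = "logical",
                 kind = "character", estimator = "character",
                 sampleUnit = "character", nFragments = "integer",
                 nCells = "integer", pixelSizeNm = "numeric"),
  prototype(pixelSizeNm = 65),
  validity = function(object) {
    n <- length(object@lags)
    msg <- character(0)
    slots <- c("values", "sem", "nProducts", "nSamples", "unitMean",
               "unitVar", "pValues", "degenerate")
    bad <- slots[vapply(slots, function(s) length(slot(object, s)) != n, TRUE)]
    if (length(bad))
      msg <- c(msg, paste0("per-lag slots must match length of 'lags': ",
                           paste(bad, collapse = ", ")))
    if (!object@kind %in% c("auto", "cross"))
      msg <- c(msg, "'kind' must be 'auto' or 'cross'")
    p <- object@pValues[is.finite(object@pValues)]
    if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve (%s, %s estimator, t-test unit: %s)\n",
              object@kind, object@estimator, object@sampleUnit))
  cat(sprintf("  lags 0..%d px (%g nm/px), %d fragments / %d cells\n",
              max(object@lags), object@pixelSizeNm, object@nFragments,
              object@nCells))
  i0 <- match(0L, object@lags)
  if (!is.na(i0))
    cat(sprintf("  value at lag 0: %.5f (p = %.3g)\n",
                object@values[i0], object@pValues[i0]))
})

#' @describeIn CorrelationCurve-class tabular view: one row per lag with
#'   columns `lag_px`, `distance_nm`, `value`, `sem`, `n_products`,
#'   `n_fragments`, `p_value`.
#' @param x a `CorrelationCurve`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @method as.data.frame CorrelationCurve
#' @export
as.data.frame.CorrelationCurve <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(lag_px = x@lags,
             distance_nm = x@lags * x@pixelSizeNm,
             value = x@values,
             sem = x@sem,
             n_products = x@nProducts,
             n_fragments = x@nFragments,
             p_value = x@pValues)
}
setMethod("as.data.frame", "CorrelationCurve", as.data.frame.CorrelationCurve)

#' SyntheticParams: parameterization of the fragment generator
#'
#' Full description of the generative model used for validation: a
#' patchy non-negative "platform" channel (smoothed, clipped Gaussian
#' texture), a focal "DSB marker" channel made of Gaussian peaks placed
#' by a Poisson point process, an optional multiplicative local
#' depletion of the platform around each focus, optional coupling of
#' focus placement to platform intensity, and additive Gaussian
#' measurement noise on both channels.
#'
#' @slot nFragments default cohort size.
#' @slot lengthRange integer c(min, max) fragment length in px.
#' @slot platformBase,platformNoiseSd,platformSmoothSigmaPx platform
#'   texture: base level, pre-smoothing Gaussian noise sd, and Gaussian
#'   smoothing sigma (px). The texture is `smooth(max(0, base + noise))`.
#' @slot focusRatePerPx Poisson intensity of foci per pixel of axis.
#' @slot focusAmp,focusSigmaPx amplitude and sigma (px) of each Gaussian
#'   focus peak.
#' @slot depletionDepth depth d in [0, 1] of the multiplicative valley
#'   `1 - d * exp(-(i - p)^2 / (2 * depletionSigmaPx^2))` carved into the
#'   platform around each focus center p.
#' @slot depletionSigmaPx width (px) of the depletion valley.
#' @slot coupling in [-1, 1]: 0 places foci uniformly; positive values
#'   bias placement toward platform peaks (rejection sampling), negative
#'   values toward platform valleys.
#' @slot couplingStrength exponential weight scale of the coupling
#'   acceptance function.
#' @slot noiseSd additive i.i.d. Gaussian noise sd per channel.
#' @slot pixelSizeNm physical pixel size (nm).
#' @slot seed RNG seed (NA = use current RNG state).
#' @exportClass SyntheticParams
setClass("SyntheticParams",
  representation(nFragments = "integer", lengthRange = "integer",
                 platformBase = "numeric", platformNoiseSd = "numeric",
                 platformSmoothSigmaPx = "numeric",
                 focusRatePerPx = "numeric", focusAmp = "numeric",
                 focusSigmaPx = "numeric", depletionDepth = "numeric",
                 depletionSigmaPx = "numeric", coupling = "numeric",
                 couplingStrength = "numeric", noiseSd = "numeric",
                 pixelSizeNm = "numeric", seed = "integer"),
  prototype(nFragments = 500L, lengthRange = c(30L, 120L),
            platformBase = 60, platformNoiseSd = 100,
            platformSmoothSigmaPx = 3, focusRatePerPx = 0.02,
            focusAmp = 120, focusSigmaPx = 3, depletionDepth = 0.7,
            depletionSigmaPx = 6, coupling = 0, couplingStrength = 4,
            noiseSd = 40, pixelSizeNm = 65, seed = NA_integer_),
  validity = function(object) {
    msg <- character(0)
    nonneg <- c("platformBase", "platformNoiseSd", "platformSmoothSigmaPx",
                "focusRatePerPx", "focusAmp", "focusSigmaPx",
                "depletionSigmaPx", "couplingStrength", "noiseSd")
    for (nm in nonneg) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v < 0)
        msg <- c(msg, sprintf("'%s' must be a single non-negative number", nm))
    }
    if (object@depletionDepth < 0 || object@depletionDepth > 1)
      msg <- c(msg, "'depletionDepth' must lie in [0, 1]")
    if (object@coupling < -1 || object@coupling > 1)
      msg <- c(msg, "'coupling' must lie in [-1, 1]")
    if (length(object@lengthRange) != 2L || any(object@lengthRange < 3L) ||
        object@lengthRange[1] > object@lengthRange[2])
      msg <- c(msg, "'lengthRange' must be c(min, max) with min >= 3")
    if (object@nFragments < 1L)
      msg <- c(msg, "'nFragments' must be >= 1")
    if (object@pixelSizeNm <= 0)
      msg <- c(msg, "'pixelSizeNm' must be positive")
    if (length(msg)) msg else TRUE
  })

#' @param ... slot values overriding the defaults; see slot documentation.
#' @rdname SyntheticParams-class
#' @export
syntheticParams <- function(...) {
  args <- list(...)
  intSlots <- c("nFragments", "lengthRange", "seed")
  for (nm in intSlots) if (nm %in% names(args))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SyntheticParams"), args))
}

setMethod("show", "SyntheticParams", function(object) {
  cat("SyntheticParams:\n")
  cat(sprintf("  %d fragments, length %d..%d px, %g nm/px, seed %s\n",
              object@nFragments, object@lengthRange[1], object@lengthRange[2],
              object@pixelSizeNm,
              ifelse(is.na(object@seed), "<current RNG>", object@seed)))
  cat(sprintf("  platform: base %g, noise sd %g, smooth sigma %g px\n",
              object@platformBase, object@platformNoiseSd,
              object@platformSmoothSigmaPx))
  cat(sprintf("  foci: rate %g /px, amp %g, sigma %g px, coupling %g\n",
              object@focusRatePerPx, object@focusAmp, object@focusSigmaPx,
              object@coupling))
  cat(sprintf("  depletion: depth %g, sigma %g px; noise sd %g\n",
              object@depletionDepth, object@depletionSigmaPx, object@noiseSd))
})

#' SyntheticFragment: one generated fragment with ground truth
#'
#' @slot platformTrue,focusTrue noiseless ground-truth vectors.
#' @slot platformObs,focusObs observed vectors (truth + noise).
#' @slot focusPositions focus center coordinates in px (possibly
#'   fractional).
#' @slot params the generating `SyntheticParams`.
#' @slot fragmentId character identifier.
#' @exportClass SyntheticFragment
setClass("SyntheticFragment",
  representation(platformTrue = "numeric", focusTrue = "numeric",
                 platformObs = "numeric", focusObs = "numeric",
                 focusPositions = "numeric", params = "SyntheticParams",
                 fragmentId = "character"),
  validity = function(object) {
    L <- length(object@platformTrue)
    if (length(object@focusTrue) != L || length(object@platformObs) != L ||
        length(object@focusObs) != L)
      return("all channel vectors must share the same length")
    TRUE
  })

setMethod("show", "SyntheticFragment", function(object) {
  cat(sprintf("SyntheticFragment %s: L = %d px, %d foci\n",
              object@fragmentId, length(object@platformTrue),
              length(object@focusPositions)))
})

#' RunConfig: configuration of a full pipeline run
#'
#' @slot mode `"synthetic"`, `"profile-table"` or `"images"`.
#' @slot primary,partner channel names: `primary` is the platform
#'   channel (the `s` series), `partner` the focus channel (`r`).
#' @slot xMax maximum lag in pixels (default 20; an additional disjoint
#'   window such as 40..43 can be requested via `extraWindow`).
#' @slot extraWindow integer c(lo, hi) extra lag window, or integer(0).
#' @slot estimator,sampleUnit passed to [correlationCurve()].
#' @slot conditions condition labels to process (for synthetic mode,
#'   preset names; empty = all conditions found).
#' @slot seed integer RNG seed recorded in every output.
#' @slot inputPath input table/image path (non-synthetic modes).
#' @slot tracesPath trace file (.roi, RoiSet .zip, or TSV) for images mode.
#' @slot columnMap named list for [importExternalTable()].
#' @slot backgroundMeans named per-channel background means (images mode).
#' @slot nFragments synthetic cohort size per condition.
#' @slot outputDir output directory.
#' @slot writePlots logical: also write PNG curve plots.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(mode = "character", primary = "character",
                 partner = "character", xMax = "integer",
                 extraWindow = "integer", estimator = "character",
                 sampleUnit = "character", conditions = "character",
                 seed = "integer", inputPath = "character",
                 tracesPath = "character", columnMap = "list",
                 backgroundMeans = "numeric", nFragments = "integer",
                 outputDir = "character", writePlots = "logical"),
  prototype(mode = "synthetic", primary = "platform", partner = "focus",
            xMax = 20L, extraWindow = integer(0),
            estimator = "fragment_mean", sampleUnit = "product",
            conditions = character(0), seed = 1L, inputPath = NA_character_,
            tracesPath = NA_character_, columnMap = list(),
            backgroundMeans = numeric(0), nFragments = 500L,
            outputDir = "axiscor-out", writePlots = FALSE),
  validity = function(object) {
    msg <- character(0)
    if (!object@mode %in% c("synthetic", "profile-table", "images"))
      msg <- c(msg, "'mode' must be one of synthetic, profile-table, images")
    if (object@xMax < 1L) msg <- c(msg, "'xMax' must be >= 1")
    if (identical(object@primary, object@partner))
      msg <- c(msg, "'primary' and 'partner' channels must be distinct")
    if (length(object@extraWindow) %in% c(0L, 2L) == FALSE)
      msg <- c(msg, "'extraWindow' must be empty or c(lo, hi)")
    if (is.na(object@seed)) msg <- c(msg, "'seed' is required")
    if (length(msg)) msg else TRUE
  })

#' @param ... slot values overriding the defaults; see slot documentation.
#' @rdname RunConfig-class
#' @export
runConfig <- function(...) {
  args <- list(...)
  for (nm in c("xMax", "extraWindow", "seed", "nFragments"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("RunConfig"), args))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: mode '%s', %s vs %s, lags 0..%d, seed %d\n",
              object@mode, object@primary, object@partner, object@xMax,
              object@seed))
})
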