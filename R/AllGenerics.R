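#' @include AllClasses.R
NULL

#' Sample a width-averaged intensity profile along a trace
#'
#' @param channel an [ImageChannel-class].
#' @param trace an [AxisTrace-class].
#' @param ... passed to methods.
#' @return numeric vector, one value per unit arc-length step.
#' @export
setGeneric("sampleProfile", function(channel, trace, ...)
  standardGeneric("sampleProfile"))

#' Mean background intensity over a set of nuclear regions
#'
#' @param channel an [ImageChannel-class].
#' @param regions a [BackgroundSet-class] (or a list/matrix accepted by
#'   [backgroundSet()]).
#' @param ... passed to methods.
#' @return scalar mean intensity over the union of region pixels.
#' @export
setGeneric("measureBackground", function(channel, regions, ...)
  standardGeneric("measureBackground"))

#' Scale a fragment's channel pair to zero mean and unit sd
#'
#' @param profile an [AxisProfile-class].
#' @param ... passed to methods.
#' @return a [ScaledFragment-class].
#' @export
setGeneric("scaleFragment", function(profile, ...)
  standardGeneric("scaleFragment"))

#' Enumerate pairwise products per axial lag
#'
#' @param frag a [ScaledFragment-class].
#' @param ... passed to methods.
#' @return a [LagProducts-class].
#' @export
setGeneric("lagProducts", function(frag, ...)
  standardGeneric("lagProducts"))

#' Generate one synthetic axis fragment
#'
#' @param params a [SyntheticParams-class].
#' @param ... passed to methods.
#' @return a [SyntheticFragment-class].
#' @export
setGeneric("generateFragment", function(params, ...)
  standardGeneric("generateFragment"))

#' Generate a synthetic cohort of axis profiles
#'
#' @param params a [SyntheticParams-class].
#' @param ... passed to methods.
#' @return list of [AxisProfile-class] with a `groundTruth` attribute.
#' @export
setGeneric("generateCohort", function(params, ...)
  standardGeneric("generateCohort"))

#' Run the full extraction/correlation/statistics pipeline
#'
#' @param config a [RunConfig-class].
#' @param ... passed to methods.
#' @export
setGeneric("runPipeline", function(config, ...)
  standardGeneric("runPipeline"))

#' Channel names of a multi-channel object
#'
#' @param x an object with named channels.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @describeIn AxisProfile-class channel names.
#' @param x an `AxisProfile`.
#' @export
setMethod("channelNames", "AxisProfile", function(x) colnames(x@intensities))

#' Intensity matrix of an AxisProfile
#'
#' @param x an [AxisProfile-class].
#' @return L x nChannels numeric matrix.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @describeIn AxisProfile-class intensity matrix accessor.
#' @export
setMethod("intensityMatrix", "AxisProfile", function(x) x@intensities)

#' Length of a fragment in pixels
#'
#' @param x an [AxisProfile-class] or [ScaledFragment-class].
#' @return integer length L.
#' @export
setGeneric("fragmentLength", function(x) standardGeneric("fragmentLength"))

setMethod("fragmentLength", "AxisProfile", function(x) nrow(x@intensities))
setMethod("fragmentLength", "ScaledFragment", function(x) length(x@s))

#' Lags, values and p-values of a correlation curve
#'
#' @param x a [CorrelationCurve-class].
#' @return numeric vector.
#' @export
setGeneric("curveLags", function(x) standardGeneric("curveLags"))
setMethod("curveLags", "CorrelationCurve", function(x) x@lags)

#' @rdname curveLags
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
setMethod("curveValues", "CorrelationCurve", function(x) x@values)

#' @rdname curveLags
#' @export
setGeneric("curvePvalues", function(x) standardGeneric("curvePvalues"))
setMethod("curvePvalues", "CorrelationCurve", function(x) x@pValues)
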