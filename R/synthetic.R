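#' @include AllClasses.R AllGenerics.R
NULL

.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Gaussian smoothing with edge renormalization (the kernel mass falling
## outside the vector is redistributed, so a constant stays constant).
.gaussSmooth <- function(x, sigma) {
  k <- .gaussKernel(sigma)
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(0, r), x, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(xp, k, sides = 2)[(r + 1):(r + n)]
  den <- stats::filter(wp, k, sides = 2)[(r + 1):(r + n)]
  as.numeric(num / den)
}

## Core generator on plain vectors; params is a SyntheticParams.
## Uses the current RNG state (callers seed it).
.genFragmentRaw <- function(params, L) {
  i <- 0:(L - 1)
  platform <- .gaussSmooth(
    pmax(0, params@platformBase +
           stats::rnorm(L, 0, params@platformNoiseSd)),
    params@platformSmoothSigmaPx)
  nFoci <- stats::rpois(1L, params@focusRatePerPx * L)
  positions <- numeric(0)
  if (nFoci > 0L) {
    cpl <- params@coupling
    if (cpl == 0) {
      positions <- stats::runif(nFoci, 0, L - 1)
    } else {
      rng <- diff(range(platform))
      u <- if (rng > 0) (platform - min(platform)) / rng else rep(0.5, L)
      w <- if (cpl > 0) u else 1 - u
      acc <- exp(params@couplingStrength * abs(cpl) * w)
      acc <- acc / max(acc)
      for (f in seq_len(nFoci)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          cand <- stats::runif(1, 0, L - 1)
          if (stats::runif(1) < acc[round(cand) + 1]) {
            positions <- c(positions, cand); placed <- TRUE; break
          }
        }
        if (!placed) {  # capped rejection loop: fall back to uniform
          warning("coupling rejection sampling hit the retry cap; ",
                  "placing focus uniformly")
          positions <- c(positions, stats::runif(1, 0, L - 1))
        }
      }
    }
  }
  depletion <- rep(1, L)
  focus <- rep(0, L)
  for (p in positions) {
    g <- exp(-(i - p)^2 / (2 * params@depletionSigmaPx^2))
    depletion <- depletion * (1 - params@depletionDepth * g)
    focus <- focus +
      params@focusAmp * exp(-(i - p)^2 / (2 * params@focusSigmaPx^2))
  }
  platformTrue <- platform * depletion
  list(platformTrue = platformTrue, focusTrue = focus,
       platformObs = platformTrue + stats::rnorm(L, 0, params@noiseSd),
       focusObs = focus + stats::rnorm(L, 0, params@noiseSd),
       positions = positions)
}

#' @describeIn generateFragment generate one fragment.
#'
#' The platform channel is `smooth(max(0, base + noise))`, multiplied by
#' `prod(1 - d * exp(-(i - p)^2 / (2 * depletionSigmaPx^2)))` over focus
#' centers p; the focus channel is a sum of Gaussian peaks of amplitude
#' `focusAmp` and width `focusSigmaPx`; the focus count is
#' Poisson(`focusRatePerPx * L`). Placement is uniform at `coupling = 0`
#' and otherwise rejection-sampled with acceptance weight exponential in
#' the normalized pre-depletion platform (positive coupling) or its
#' complement (negative coupling), with a capped retry loop falling back
#' to uniform. Finally i.i.d. Gaussian noise is added to both channels.
#' Draws from the current RNG state; seed it (or use [generateCohort()],
#' which honours `params@seed`) for reproducibility.
#'
#' @param L fragment length in px; default: drawn uniformly from
#'   `params@lengthRange`.
#' @param fragmentId identifier.
#' @export
setMethod("generateFragment", "SyntheticParams",
  function(params, L = NULL, fragmentId = "synthetic", ...) {
    if (is.null(L))
      L <- sample(params@lengthRange[1]:params@lengthRange[2], 1L)
    raw <- .genFragmentRaw(params, as.integer(L))
    new("SyntheticFragment", platformTrue = raw$platformTrue,
        focusTrue = raw$focusTrue, platformObs = raw$platformObs,
        focusObs = raw$focusObs, focusPositions = raw$positions,
        params = params, fragmentId = fragmentId)
  })

#' @describeIn generateCohort generate a cohort of AxisProfile objects.
#'
#' Fragment lengths are i.i.d. uniform on `params@lengthRange`. The
#' profiles carry channels `"platform"` and `"focus"` (observed, i.e.
#' with noise) and are consumed unchanged by the correlation stage. The
#' ground truth (focus positions and noiseless vectors) is attached as
#' `attr(, "groundTruth")`, a list with one entry per fragment, and can
#' be written to a JSON sidecar by [writeCohort()]. When `params@seed`
#' is not NA the RNG is seeded, so a fixed seed gives an identical
#' cohort on every call.
#'
#' @param nFragments cohort size (default `params@nFragments`).
#' @param condition condition label stored in the profiles.
#' @param cellsOf number of fragments per nominal cell identifier
#'   (cohorts are grouped into pseudo-cells of this size; default 10,
#'   matching the handful of traceable axes per spread).
#' @export
setMethod("generateCohort", "SyntheticParams",
  function(params, nFragments = params@nFragments, condition = "synthetic",
           cellsOf = 10L, ...) {
    stopifnot(nFragments >= 1L)
    if (!is.na(params@seed)) set.seed(params@seed)
    lens <- sample(params@lengthRange[1]:params@lengthRange[2],
                   nFragments, replace = TRUE)
    profiles <- vector("list", nFragments)
    truth <- vector("list", nFragments)
    for (f in seq_len(nFragments)) {
      raw <- .genFragmentRaw(params, lens[f])
      m <- cbind(platform = raw$platformObs, focus = raw$focusObs)
      fid <- sprintf("frag%04d", f)
      cid <- sprintf("cell%03d", (f - 1L) %/% as.integer(cellsOf) + 1L)
      profiles[[f]] <- axisProfile(m, cellId = cid, fragmentId = fid,
                                   condition = condition,
                                   pixelSizeNm = params@pixelSizeNm)
      truth[[f]] <- list(fragment_id = fid,
                         focus_positions = raw$positions,
                         platform_true = raw$platformTrue,
                         focus_true = raw$focusTrue)
    }
    attr(profiles, "groundTruth") <- truth
    profiles
  })

#' Named parameter presets for the qualitative regimes of the assay
#'
#' The presets reproduce, on synthetic cohorts, the qualitative
#' cross-correlation regimes the analysis distinguishes on real
#' spermatocyte spreads: a clear negative g(0) when DSB foci locally
#' deplete the platform channel (`wt_like`), a null g(0) when depletion
#' is absent (`atr_null_like`, and `irradiation_1h_like` for freshly
#' induced, uniformly placed DSB foci), and a weak positive g(0) when
#' foci sit preferentially on platform-rich axis without depleting it
#' (`atr_atm_null_like`). The generator is a stand-in for validation,
#' not a fit: no claim is made of estimating biological parameters.
#'
#' @return named list of [SyntheticParams-class].
#' @examples
#' names(genotypePresets())
#' @export
genotypePresets <- function() {
  base <- syntheticParams()
  mod <- function(...) {
    args <- list(...)
    for (nm in names(args)) slot(base, nm) <- args[[nm]]
    validObject(base)
    base
  }
  list(
    wt_like            = mod(depletionDepth = 0.7, coupling = 0),
    atr_null_like      = mod(depletionDepth = 0,   coupling = 0),
    atr_atm_null_like  = mod(depletionDepth = 0,   coupling = 0.5),
    irradiation_1h_like = mod(depletionDepth = 0,  coupling = 0)
  )
}

#' Look up one preset by name
#'
#' @param name preset name; unknown names are an error.
#' @return a [SyntheticParams-class].
#' @export
getPreset <- function(name) {
  presets <- genotypePresets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Serialize SyntheticParams to a plain list (and back)
#'
#' Round-trips through YAML/JSON configuration files.
#'
#' @param params a [SyntheticParams-class].
#' @return named list of slot values.
#' @export
paramsToList <- function(params) {
  nms <- slotNames("SyntheticParams")
  out <- lapply(nms, function(nm) slot(params, nm))
  names(out) <- nms
  out
}

#' @rdname paramsToList
#' @param x named list as produced by [paramsToList()].
#' @export
paramsFromList <- function(x) {
  do.call(syntheticParams, x[names(x) %in% slotNames("SyntheticParams")])
}

#' Render a cohort of fragments into a synthetic image
#'
#' Paints each fragment's channels along a straight horizontal line in a
#' blank image (one row per fragment, separated by `gapRows`), blurs
#' each channel with an isotropic Gaussian point-spread function and
#' adds a constant background offset. Returns the image channels
#' together with the ground-truth traces, so
#' [extractProfiles()] round-trips the generator output.
#'
#' @param profiles list of [AxisProfile-class] (e.g. from
#'   [generateCohort()]).
#' @param psfSigmaPx PSF sigma in px (0 = no blur).
#' @param background constant background offset added to every pixel.
#' @param margin blank border in px.
#' @param gapRows vertical spacing between fragment rows.
#' @param widthPx sampling width recorded in the returned traces.
#' @param dim optional c(nrow, ncol); an image too small to hold the
#'   layout is an error.
#' @return list with elements `channels` (named [ImageChannel-class]
#'   list) and `traces` (list of [AxisTrace-class]).
#' @export
renderImage <- function(profiles, psfSigmaPx = 1, background = 10,
                        margin = 10L, gapRows = 9L, widthPx = 1L,
                        dim = NULL) {
  nf <- length(profiles)
  chans <- if (nf) channelNames(profiles[[1]]) else c("platform", "focus")
  maxL <- if (nf) max(vapply(profiles, fragmentLength, 0L)) else 1L
  needR <- 2L * margin + max(0L, nf - 1L) * gapRows + 1L
  needC <- 2L * margin + maxL
  if (is.null(dim)) dim <- c(needR, needC)
  if (dim[1] < needR || dim[2] < needC)
    stop(sprintf("image %d x %d too small for layout (needs %d x %d)",
                 dim[1], dim[2], needR, needC))
  px <- lapply(chans, function(ch) matrix(0, dim[1], dim[2]))
  names(px) <- chans
  traces <- vector("list", nf)
  for (f in seq_len(nf)) {
    pr <- profiles[[f]]
    L <- fragmentLength(pr)
    r0 <- margin + (f - 1L) * gapRows
    cols <- margin + 0:(L - 1)
    for (ch in chans)
      ## intensities can dip below zero after noise; images are physical
      px[[ch]][r0 + 1L, cols + 1L] <- pmax(0, pr@intensities[, ch])
    traces[[f]] <- axisTrace(rbind(c(r0, margin), c(r0, margin + L - 1)),
                             widthPx = widthPx, cellId = pr@cellId,
                             fragmentId = pr@fragmentId)
  }
  if (psfSigmaPx > 0) {
    k <- .gaussKernel(psfSigmaPx)
    blur2d <- function(m) {
      m <- apply(m, 2, function(col) .gaussSmoothOpen(col, k))
      t(apply(m, 1, function(row) .gaussSmoothOpen(row, k)))
    }
    px <- lapply(px, blur2d)
  }
  channels <- lapply(chans, function(ch)
    imageChannel(px[[ch]] + background, ch,
                 if (nf) profiles[[1]]@pixelSizeNm else 65))
  names(channels) <- chans
  list(channels = channels, traces = traces)
}

## zero-padded convolution (no renormalization): light leaving the field
## of view is lost, as in a real PSF
.gaussSmoothOpen <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(0, r), x, rep(0, r))
  as.numeric(stats::filter(xp, k, sides = 2)[(r + 1):(r + n)])
}

#' Write a cohort as a profile table plus ground-truth JSON sidecar
#'
#' @param profiles list of [AxisProfile-class] from [generateCohort()].
#' @param path output TSV; the sidecar is written to `<path>.truth.json`
#'   and records focus positions, true vectors and the full parameters.
#' @param params the generating [SyntheticParams-class] (recorded in the
#'   sidecar when given).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(profiles, path, params = NULL) {
  writeProfileTable(profiles, path)
  truth <- attr(profiles, "groundTruth")
  payload <- list(ground_truth = truth)
  if (!is.null(params)) payload$params <- paramsToList(params)
  jsonlite::write_json(payload, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
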