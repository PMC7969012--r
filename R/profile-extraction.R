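#' @include AllClasses.R AllGenerics.R
NULL

## Bilinear interpolation at fractional (row, col) coordinates, 0-based,
## pixel centers at integers. Coordinates must already be within bounds.
.bilinear <- function(pixels, rr, cc) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  r0 <- floor(rr); c0 <- floor(cc)
  r0[r0 > nr - 2] <- nr - 2L
  c0[c0 > nc - 2] <- nc - 2L
  if (nr == 1L) r0[] <- 0L
  if (nc == 1L) c0[] <- 0L
  fr <- rr - r0; fc <- cc - c0
  i00 <- r0 + 1L + nr * c0
  i10 <- i00 + ifelse(nr > 1L, 1L, 0L)
  i01 <- i00 + ifelse(nc > 1L, nr, 0L)
  i11 <- i01 + ifelse(nr > 1L, 1L, 0L)
  p <- pixels
  (1 - fr) * (1 - fc) * p[i00] + fr * (1 - fc) * p[i10] +
    (1 - fr) * fc * p[i01] + fr * fc * p[i11]
}

## Resample a polyline at unit arc-length steps. Returns positions and
## unit direction of the segment each position falls on.
.traceSteps <- function(vertices) {
  d <- diff(vertices)
  seglen <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  tpos <- seq(0, floor(total), by = 1)
  seg <- findInterval(tpos, cum, rightmost.closed = TRUE, all.inside = TRUE)
  frac <- (tpos - cum[seg]) / seglen[seg]
  pts <- vertices[seg, , drop = FALSE] + frac * d[seg, , drop = FALSE]
  dir <- d[seg, , drop = FALSE] / seglen[seg]
  list(points = pts, dir = dir)
}

#' @describeIn sampleProfile Width-averaged sampling along a polyline.
#'
#' The trace is resampled at unit (1 px) arc-length steps; the output has
#' `floor(total arc length) + 1` values, indexed from position 0. At each
#' step, `widthPx` samples are taken at unit spacing along the local
#' normal, centered on the trace, each by bilinear interpolation, and
#' averaged. This mirrors how ImageJ's wide-line `getProfile` averages
#' intensities over the line width without replicating its internals
#' bit-for-bit.
#'
#' All sampling positions (after width expansion) must lie inside the
#' image; an out-of-bounds trace is an error rather than being clipped.
#' @export
setMethod("sampleProfile", signature("ImageChannel", "AxisTrace"),
  function(channel, trace, ...) {
    w <- trace@widthPx
    if (w %% 2L == 0L)
      stop("invalid width: 'widthPx' must be odd, got ", w)
    st <- .traceSteps(trace@vertices)
    offsets <- seq.int(-(w - 1L) / 2L, (w - 1L) / 2L)
    normal <- cbind(-st$dir[, 2], st$dir[, 1])
    n <- nrow(st$points)
    px <- channel@pixels
    nr <- nrow(px); nc <- ncol(px)
    acc <- numeric(n)
    for (o in offsets) {
      rr <- st$points[, 1] + o * normal[, 1]
      cc <- st$points[, 2] + o * normal[, 2]
      eps <- 1e-9
      if (any(rr < -eps | rr > nr - 1 + eps | cc < -eps | cc > nc - 1 + eps))
        stop(sprintf(
          "trace '%s' leaves the %d x %d image after width expansion (width %d)",
          trace@fragmentId, nr, nc, w))
      rr <- pmin(pmax(rr, 0), nr - 1)
      cc <- pmin(pmax(cc, 0), nc - 1)
      acc <- acc + .bilinear(px, rr, cc)
    }
    acc / length(offsets)
  })

## Even-odd (ray casting) point-in-polygon test for pixel centers.
.polygonMask <- function(vertices, dim) {
  nr <- dim[1]; nc <- dim[2]
  ctr <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  y <- ctr$row + 1e-7  # nudge off edges so boundary handling is consistent
  x <- ctr$col + 1e-7
  inside <- rep(FALSE, length(x))
  vy <- vertices[, 1]; vx <- vertices[, 2]
  m <- length(vy)
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((vy[i] > y) != (vy[j] > y)) &
      (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' @describeIn measureBackground Mean intensity over the union of
#'   region pixels. Polygon regions are rasterized at pixel centers;
#'   overlapping regions are counted once (union semantics).
#' @export
setMethod("measureBackground", signature("ImageChannel", "BackgroundSet"),
  function(channel, regions, ...) {
    dims <- dim(channel@pixels)
    mask <- matrix(FALSE, dims[1], dims[2])
    for (rg in regions@regions) {
      if (is.logical(rg)) {
        if (!all(dim(rg) == dims))
          stop("mask region dimensions do not match the image")
        m <- rg
      } else {
        if (any(rg[, 1] < -0.5 | rg[, 1] > dims[1] - 0.5 |
                rg[, 2] < -0.5 | rg[, 2] > dims[2] - 0.5))
          stop("background region extends outside the image")
        m <- .polygonMask(rg, dims)
      }
      if (!any(m)) stop("a background region contains no pixels")
      mask <- mask | m
    }
    mean(channel@pixels[mask])
  })

#' @describeIn measureBackground convenience: wraps plain lists/matrices
#'   with [backgroundSet()].
#' @export
setMethod("measureBackground", signature("ImageChannel", "ANY"),
  function(channel, regions, ...) {
    measureBackground(channel, backgroundSet(regions), ...)
  })

#' Subtract a scalar background from a profile vector
#'
#' Elementwise subtraction; negative values are retained, not clipped
#' (per-fragment scaling removes the mean downstream anyway).
#'
#' @param profile numeric intensity vector.
#' @param background finite scalar background mean.
#' @return numeric vector of the same length.
#' @export
subtractBackground <- function(profile, background) {
  stopifnot(is.numeric(profile), length(background) == 1L)
  if (!is.finite(background)) stop("background mean must be finite")
  profile - background
}

#' Extract background-subtracted profiles for a set of traces
#'
#' Composes [sampleProfile()], [measureBackground()] and
#' [subtractBackground()]: every channel is sampled along the identical
#' trace geometry and each channel is corrected with its own background.
#'
#' @param channels named list of [ImageChannel-class] objects sharing
#'   dimensions.
#' @param traces list of [AxisTrace-class] objects (or a single trace).
#' @param backgrounds either a named numeric vector of per-channel
#'   background means, a single [BackgroundSet-class] applied to every
#'   channel, or `NULL` (no subtraction).
#' @param condition condition label stored in each profile.
#' @return list of [AxisProfile-class], one per trace.
#' @export
extractProfiles <- function(channels, traces, backgrounds = NULL,
                            condition = "na") {
  if (is(channels, "ImageChannel")) channels <- list(channels)
  if (is(traces, "AxisTrace")) traces <- list(traces)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- vapply(channels, function(ch) ch@channelName, "")
  dims <- dim(channels[[1]]@pixels)
  for (ch in channels) if (!all(dim(ch@pixels) == dims))
    stop("all channels must share image dimensions")
  bg <- rep(0, length(channels))
  names(bg) <- names(channels)
  if (is(backgrounds, "BackgroundSet")) {
    bg[] <- vapply(channels, measureBackground, 0, regions = backgrounds)
  } else if (is.numeric(backgrounds) && length(backgrounds)) {
    if (!is.null(names(backgrounds))) {
      miss <- setdiff(names(channels), names(backgrounds))
      if (length(miss))
        stop("no background given for channel(s): ", paste(miss, collapse = ", "))
      bg[] <- backgrounds[names(channels)]
    } else {
      stopifnot(length(backgrounds) == length(channels))
      bg[] <- backgrounds
    }
  }
  lapply(traces, function(tr) {
    vals <- vapply(names(channels), function(nm)
      subtractBackground(sampleProfile(channels[[nm]], tr), bg[[nm]]),
      numeric(length(sampleProfile(channels[[1]], tr))))
    axisProfile(vals, cellId = tr@cellId, fragmentId = tr@fragmentId,
                condition = condition,
                pixelSizeNm = channels[[1]]@pixelSizeNm)
  })
}

#' Read a grayscale multi-channel TIFF as ImageChannel objects
#'
#' Reads a single- or multi-page grayscale TIFF (8/16-bit or 32-bit).
#' When a `<path>.json` sidecar written by [writeImageChannels()] is
#' present, channel names, pixel size and the intensity scale are taken
#' from it; otherwise integer TIFFs are returned on their native scale
#' (0..255 for 8-bit, 0..65535 for 16-bit).
#'
#' @param path TIFF file.
#' @param channelNames labels for the pages; overrides the sidecar
#'   (default names `ch1`, `ch2`, ... when neither is given).
#' @param pixelSizeNm physical pixel size in nm (default 65).
#' @return named list of [ImageChannel-class] objects.
#' @export
readImageChannels <- function(path, channelNames = NULL, pixelSizeNm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # grayscale stored with 1 plane
    p
  })
  sidecar <- paste0(path, ".json")
  scale <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$scale
    if (is.null(channelNames)) channelNames <- meta$channels
    if (is.null(pixelSizeNm)) pixelSizeNm <- meta$pixel_size_nm
  }
  if (is.null(scale)) {
    bits <- attr(pages[[1]], "bits.per.sample")
    scale <- if (is.null(bits)) 1 else 2^bits - 1
  }
  if (is.null(pixelSizeNm)) pixelSizeNm <- 65
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_along(pages))
  stopifnot(length(channelNames) == length(pages))
  out <- Map(function(p, nm) {
    m <- matrix(as.numeric(p) * scale, nrow(p), ncol(p))  # drop TIFF attrs
    imageChannel(m, nm, pixelSizeNm)
  }, pages, channelNames)
  names(out) <- channelNames
  out
}

#' Write ImageChannel objects as a multi-page TIFF plus JSON sidecar
#'
#' Intensities are normalized by a common scale (recorded, together with
#' channel names and pixel size, in a `<path>.json` sidecar) and stored
#' as 32-bit samples, so [readImageChannels()] round-trips arbitrary
#' intensity units to within 32-bit quantization.
#'
#' @param channels named list of [ImageChannel-class] (or one channel).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImageChannels <- function(channels, path) {
  if (is(channels, "ImageChannel")) channels <- list(channels)
  scale <- max(1e-12, vapply(channels, function(ch) max(ch@pixels), 0))
  mats <- lapply(channels, function(ch) ch@pixels / scale)
  tiff::writeTIFF(mats, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale,
         channels = vapply(channels, function(ch) ch@channelName, ""),
         pixel_size_nm = channels[[1]]@pixelSizeNm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
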