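#' @include AllClasses.R
NULL

## ImageJ ROI type codes (ij.io.RoiDecoder)
.ROI_POLYGON  <- 0L
.ROI_RECT     <- 1L
.ROI_OVAL     <- 2L
.ROI_LINE     <- 3L
.ROI_FREELINE <- 4L
.ROI_POLYLINE <- 5L
.ROI_FREEHAND <- 7L
.ROI_SUBPIXEL <- 128L  # options flag

#' Read a single ImageJ ROI record
#'
#' Minimal reader for the binary `.roi` format written by ImageJ's ROI
#' Manager ("Iout" records, big-endian). Line-like ROIs (polyline,
#' freeline, segmented line) become [AxisTrace-class] objects; area ROIs
#' (polygon, freehand selection, rectangle) are returned as n x 2
#' (row, col) vertex matrices suitable for [backgroundSet()]. Sub-pixel
#' coordinates are used when the record carries them. The ImageJ (x, y)
#' convention maps to this package's (row, col) as row = y, col = x,
#' both 0-based.
#'
#' @param path a `.roi` file.
#' @param widthPx sampling width for traces; defaults to the ROI's
#'   stroke width when that is an odd positive integer, else 5.
#' @param cellId,fragmentId identifiers (default: file name).
#' @return an [AxisTrace-class] or a numeric polygon matrix.
#' @export
readImageJRoi <- function(path, widthPx = NULL, cellId = "cell",
                          fragmentId = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file: ", path)
  getShort <- function(off)  # 0-based byte offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  type <- as.integer(raw[7])
  top <- getShort(8); left <- getShort(10)
  n <- getShort(16)
  options <- getShort(50)
  strokeWidth <- getShort(34)
  if (type == .ROI_RECT) {
    bottom <- getShort(12); right <- getShort(14)
    verts <- cbind(row = c(top, top, bottom - 1, bottom - 1),
                   col = c(left, right - 1, right - 1, left))
  } else {
    if (n < 1L) stop("ROI record contains no coordinates: ", path)
    subpixel <- bitwAnd(options, .ROI_SUBPIXEL) != 0L && length(raw) >= 64 + 8 * n
    if (subpixel) {
      off <- 64 + 4 * n
      fx <- readBin(raw[(off + 1):(off + 4 * n)], "double", n = n,
                    size = 4, endian = "big")
      fy <- readBin(raw[(off + 4 * n + 1):(off + 8 * n)], "double", n = n,
                    size = 4, endian = "big")
      verts <- cbind(row = fy, col = fx)
    } else {
      xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                    endian = "big")
      ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n,
                    size = 2, endian = "big")
      verts <- cbind(row = top + ys, col = left + xs)
    }
  }
  if (is.null(fragmentId))
    fragmentId <- sub("\\.roi$", "", basename(path))
  if (type %in% c(.ROI_POLYLINE, .ROI_FREELINE, .ROI_LINE)) {
    ## drop zero-length duplicate steps freehand tracing can produce
    keep <- c(TRUE, rowSums(diff(verts)^2) > 0)
    verts <- verts[keep, , drop = FALSE]
    if (is.null(widthPx)) {
      widthPx <- if (strokeWidth >= 1L && strokeWidth %% 2L == 1L)
        strokeWidth else 5L
    }
    axisTrace(verts, widthPx = widthPx, cellId = cellId,
              fragmentId = fragmentId)
  } else if (type %in% c(.ROI_POLYGON, .ROI_FREEHAND, .ROI_RECT)) {
    storage.mode(verts) <- "double"
    verts
  } else {
    stop("unsupported ImageJ ROI type code ", type, " in ", path)
  }
}

#' Read every ROI in an ImageJ RoiSet zip archive
#'
#' @param path a `RoiSet.zip` written by ImageJ's ROI Manager.
#' @param ... passed to [readImageJRoi()].
#' @return named list of traces/polygons, one per `.roi` member.
#' @export
readRoiSet <- function(path, ...) {
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files)])
  if (!length(files)) stop("no .roi members found in ", path)
  out <- lapply(files, readImageJRoi, ...)
  names(out) <- sub("\\.roi$", "", basename(files))
  out
}

#' Write a minimal ImageJ ROI record
#'
#' Writes polyline (from an [AxisTrace-class]) or polygon (from an
#' n x 2 vertex matrix) records that ImageJ and [readImageJRoi()] can
#' read. Coordinates are stored with sub-pixel resolution.
#'
#' @param x an [AxisTrace-class] or an n x 2 (row, col) matrix.
#' @param path output `.roi` file.
#' @return `path`, invisibly.
#' @export
writeImageJRoi <- function(x, path) {
  isTrace <- is(x, "AxisTrace")
  verts <- if (isTrace) x@vertices else as.matrix(x)
  type <- if (isTrace) .ROI_POLYLINE else .ROI_POLYGON
  n <- nrow(verts)
  rows <- verts[, 1]; cols <- verts[, 2]
  top <- floor(min(rows)); left <- floor(min(cols))
  bottom <- ceiling(max(rows)) + 1; right <- ceiling(max(cols)) + 1
  hdr <- raw(64)
  hdr[1:4] <- charToRaw("Iout")
  putShort <- function(buf, off, val) {
    buf[(off + 1):(off + 2)] <- writeBin(as.integer(val), raw(), size = 2,
                                         endian = "big")
    buf
  }
  hdr <- putShort(hdr, 4, 228L)          # version
  hdr[7] <- as.raw(type)
  hdr <- putShort(hdr, 8, top);    hdr <- putShort(hdr, 10, left)
  hdr <- putShort(hdr, 12, bottom); hdr <- putShort(hdr, 14, right)
  hdr <- putShort(hdr, 16, n)
  if (isTrace) hdr <- putShort(hdr, 34, x@widthPx)
  hdr <- putShort(hdr, 50, .ROI_SUBPIXEL)  # options: sub-pixel resolution
  ints <- function(v, base) writeBin(as.integer(round(v - base)), raw(),
                                     size = 2, endian = "big")
  floats <- function(v) writeBin(as.numeric(v), raw(), size = 4,
                                 endian = "big")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(c(ints(cols, left), ints(rows, top)), con)
  writeBin(c(floats(cols), floats(rows)), con)
  invisible(path)
}

#' Read axis traces from the plain-text fallback format
#'
#' One vertex per line, three tab-separated columns
#' `fragment_id<TAB>row<TAB>col` (header optional; additional columns
#' `cell_id` and `width_px` are honoured when present). Vertices of a
#' fragment must be listed consecutively in drawing order.
#'
#' @param path TSV file.
#' @param widthPx default sampling width when the file has no
#'   `width_px` column.
#' @return list of [AxisTrace-class].
#' @export
readTraceTable <- function(path, widthPx = 5L) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("fragment", tolower(first))
  tab <- utils::read.table(path, sep = "\t", header = hasHeader,
                           stringsAsFactors = FALSE)
  if (!hasHeader)
    names(tab)[1:3] <- c("fragment_id", "row", "col")
  need <- c("fragment_id", "row", "col")
  if (!all(need %in% names(tab)))
    stop("trace table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(tab$fragment_id)
  lapply(ids, function(id) {
    sub <- tab[tab$fragment_id == id, , drop = FALSE]
    w <- if ("width_px" %in% names(sub)) sub$width_px[1] else widthPx
    cid <- if ("cell_id" %in% names(sub)) as.character(sub$cell_id[1]) else "cell"
    axisTrace(cbind(row = sub$row, col = sub$col), widthPx = w,
              cellId = cid, fragmentId = as.character(id))
  })
}

#' Write axis traces in the plain-text fallback format
#'
#' @param traces list of [AxisTrace-class] (or a single trace).
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writeTraceTable <- function(traces, path) {
  if (is(traces, "AxisTrace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(fragment_id = tr@fragmentId, row = tr@vertices[, 1],
               col = tr@vertices[, 2], cell_id = tr@cellId,
               width_px = tr@widthPx)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
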