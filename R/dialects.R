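#' @include AllClasses.R
NULL

#' Write axis profiles in the profile-table TSV dialect
#'
#' One row per position with columns `condition`, `cell_id`,
#' `fragment_id`, `position_px`, then one column per channel; header
#' mandatory, UTF-8, tab-separated. Positions are contiguous per
#' fragment starting at 0.
#'
#' @param profiles list of [AxisProfile-class] (or a single profile).
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  if (is(profiles, "AxisProfile")) profiles <- list(profiles)
  chans <- channelNames(profiles[[1]])
  rows <- lapply(profiles, function(pr) {
    stopifnot(identical(channelNames(pr), chans))
    L <- fragmentLength(pr)
    cbind(data.frame(condition = pr@condition, cell_id = pr@cellId,
                     fragment_id = pr@fragmentId, position_px = 0:(L - 1)),
          as.data.frame(pr@intensities))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a profile-table TSV written by [writeProfileTable()]
#'
#' @param path TSV file.
#' @param pixelSizeNm pixel size recorded in the profiles (default 65).
#' @return list of [AxisProfile-class].
#' @export
readProfileTable <- function(path, pixelSizeNm = 65) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("condition", "cell_id", "fragment_id", "position_px")
  if (!all(need %in% names(tab)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  chans <- setdiff(names(tab), need)
  if (!length(chans)) stop("profile table has no channel columns")
  key <- paste(tab$condition, tab$cell_id, tab$fragment_id, sep = "\r")
  idx <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    sub <- tab[i, , drop = FALSE]
    sub <- sub[order(sub$position_px), , drop = FALSE]
    if (!identical(as.integer(sub$position_px), 0:(nrow(sub) - 1L)))
      stop("positions of fragment '", sub$fragment_id[1],
           "' are not contiguous from 0; use importExternalTable() ",
           "to split fragments at gaps")
    m <- as.matrix(sub[, chans, drop = FALSE])
    axisProfile(m, cellId = as.character(sub$cell_id[1]),
                fragmentId = as.character(sub$fragment_id[1]),
                condition = as.character(sub$condition[1]),
                pixelSizeNm = pixelSizeNm)
  })
}

.sniffDelimiter <- function(lines) {
  counts <- vapply(c("\t", ",", ";"), function(d)
    sum(lengths(strsplit(lines, d, fixed = TRUE)) - 1L), 0L)
  names(which.max(counts))
}

#' Import an externally produced intensity table as axis profiles
#'
#' Reads pre-extracted, background-subtracted per-fragment intensity
#' tables (e.g. spreadsheet sheets exported to TSV/CSV) through a
#' user-supplied column mapping, since external layouts vary. The
#' delimiter is sniffed (tab, comma or semicolon) and decimal commas
#' are tolerated. Fragments whose positions have gaps are split at the
#' gaps into separate fragments (with a message counting the splits);
#' zero-variance fragments are kept here and flagged, to be excluded by
#' [scaleCohort()].
#'
#' @param path delimited text file.
#' @param columnMap named list with entries `fragment` (required),
#'   `channels` (required: named character vector mapping channel name
#'   to source column), and optionally `condition`, `cell`, `position`.
#'   When `position` is omitted, row order within a fragment is used.
#'   When `condition`/`cell` are omitted, `defaultCondition` and the
#'   fragment id are used.
#' @param defaultCondition condition label when the table has none.
#' @param pixelSizeNm pixel size recorded in the profiles.
#' @return list of [AxisProfile-class]; fragments with a zero-variance
#'   channel carry `attr(, "zeroVariance") = TRUE`.
#' @export
importExternalTable <- function(path, columnMap, defaultCondition = "na",
                                pixelSizeNm = 65) {
  stopifnot(is.list(columnMap))
  for (req in c("fragment", "channels"))
    if (is.null(columnMap[[req]]))
      stop("columnMap must name the '", req, "' column(s)")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  delim <- .sniffDelimiter(lines[seq_len(min(10, length(lines)))])
  dec <- "."
  if (delim != "," &&
      any(grepl("(^|\\D)\\d+,\\d+(\\D|$)", lines[-1][seq_len(min(10, length(lines) - 1))])))
    dec <- ","
  tab <- utils::read.table(text = lines, sep = delim, dec = dec,
                           header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  pick <- function(role) {
    col <- columnMap[[role]]
    if (is.null(col)) return(NULL)
    if (!col %in% names(tab))
      stop("column '", col, "' (", role, ") not found; available: ",
           paste(names(tab), collapse = ", "))
    tab[[col]]
  }
  fragment <- as.character(pick("fragment"))
  condition <- pick("condition")
  condition <- if (is.null(condition)) rep(defaultCondition, nrow(tab))
    else as.character(condition)
  cell <- pick("cell")
  cell <- if (is.null(cell)) fragment else as.character(cell)
  position <- pick("position")
  chanCols <- columnMap$channels
  if (is.null(names(chanCols))) names(chanCols) <- chanCols
  for (col in chanCols) if (!col %in% names(tab))
    stop("channel column '", col, "' not found; available: ",
         paste(names(tab), collapse = ", "))
  chanMat <- do.call(cbind, lapply(chanCols, function(col)
    as.numeric(tab[[col]])))
  key <- paste(condition, cell, fragment, sep = "\r")
  idx <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  profiles <- list()
  nSplit <- 0L; nZeroVar <- 0L; nShort <- 0L
  for (i in idx) {
    pos <- if (is.null(position)) seq_along(i) - 1L
      else as.integer(position[i])
    o <- order(pos)
    i <- i[o]; pos <- pos[o]
    ## split at position gaps
    runStart <- c(TRUE, diff(pos) != 1L)
    runId <- cumsum(runStart)
    if (max(runId) > 1L) nSplit <- nSplit + 1L
    for (rid in unique(runId)) {
      sel <- i[runId == rid]
      if (length(sel) < 2L) { nShort <- nShort + 1L; next }
      m <- chanMat[sel, , drop = FALSE]
      colnames(m) <- names(chanCols)
      fid <- fragment[sel[1]]
      if (max(runId) > 1L) fid <- paste0(fid, ".", rid)
      pr <- axisProfile(m, cellId = cell[sel[1]], fragmentId = fid,
                        condition = condition[sel[1]],
                        pixelSizeNm = pixelSizeNm)
      if (any(apply(m, 2, stats::sd) == 0)) {
        attr(pr, "zeroVariance") <- TRUE
        nZeroVar <- nZeroVar + 1L
      }
      profiles[[length(profiles) + 1L]] <- pr
    }
  }
  message(sprintf(
    "imported %d fragment(s) from %s (%d split at gaps, %d zero-variance flagged, %d too-short run(s) dropped)",
    length(profiles), basename(path), nSplit, nZeroVar, nShort))
  profiles
}

#' Convert pixel lags to physical distances
#'
#' @param lagsPx integer lag(s) in pixels.
#' @param pixelSizeNm physical pixel size in nm (default 65, i.e.
#'   lag 5 = 325 nm, lag 10 = 650 nm = 0.65 um).
#' @return data.frame with columns `lag_px`, `distance_nm`,
#'   `distance_um`.
#' @export
distanceAxis <- function(lagsPx, pixelSizeNm = 65) {
  stopifnot(pixelSizeNm > 0)
  data.frame(lag_px = lagsPx, distance_nm = lagsPx * pixelSizeNm,
             distance_um = lagsPx * pixelSizeNm / 1000)
}

#' Write a correlation curve as TSV plus JSON sidecar
#'
#' The TSV has columns `lag_px`, `distance_nm`, `value`, `sem`,
#' `n_products`, `n_fragments`, `p_value`; the `<path>.json` sidecar
#' records estimator, sample unit, lag range, counts and an input
#' digest.
#'
#' @param curve a [CorrelationCurve-class].
#' @param path output TSV file.
#' @param inputDigest optional digest string identifying the inputs.
#' @return `path`, invisibly.
#' @export
writeCurveTable <- function(curve, path, inputDigest = NA_character_) {
  df <- as.data.frame(curve)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(kind = curve@kind, estimator = curve@estimator,
         sample_unit = curve@sampleUnit, x_max = max(curve@lags),
         n_fragments = curve@nFragments, n_cells = curve@nCells,
         pixel_size_nm = curve@pixelSizeNm, input_digest = inputDigest),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
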