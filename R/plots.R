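#' @include AllClasses.R
NULL

#' Plot a correlation curve with error bars and a significance track
#'
#' Curve values with per-lag standard-error bars over axial distance in
#' pixels, plus a lower track showing per-lag significance as
#' log10(p-value), mirroring how such panels are usually presented.
#' Plotting is cosmetic; all quantities come from the
#' [CorrelationCurve-class] unchanged.
#'
#' @param curve a [CorrelationCurve-class].
#' @param main plot title.
#' @param col curve color.
#' @param pTrack logical: draw the log10(p) track (default TRUE).
#' @return invisibly, the data.frame behind the plot.
#' @export
plotCurve <- function(curve, main = NULL, col = "firebrick",
                      pTrack = TRUE) {
  df <- as.data.frame(curve)
  if (is.null(main))
    main <- sprintf("%s-correlation (%d fragments)",
                    curve@kind, curve@nFragments)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (pTrack) graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  ylim <- range(c(df$value - df$sem, df$value + df$sem, 0))
  graphics::plot(df$lag_px, df$value, type = "b", pch = 16, col = col,
                 ylim = ylim, xlab = "axial distance (px)",
                 ylab = if (curve@kind == "auto") "c(x)" else "g(x)",
                 main = main)
  graphics::arrows(df$lag_px, df$value - df$sem, df$lag_px,
                   df$value + df$sem, angle = 90, code = 3,
                   length = 0.02, col = col)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  if (pTrack) {
    lp <- log10(pmax(df$p_value, 1e-300))
    graphics::par(mar = c(4, 4, 0.5, 1))
    graphics::plot(df$lag_px, lp, type = "h", lwd = 3, col = "grey30",
                   xlab = "axial distance (px)",
                   ylab = "log10 p-value")
    graphics::abline(h = log10(0.05), lty = 2, col = "red")
  }
  invisible(df)
}
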