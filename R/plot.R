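#' Plot a QRE trace with the Nash curve
#'
#' Basic strategy-plane view: the traced QRE points, the derived Nash curve,
#' and optionally a set of estimated strategy points.
#'
#' @param trace A [trace_qre()] result.
#' @param nash Overlay the derived Nash curve.
#' @param points Optional data frame with `alpha_hat`, `gamma_hat` columns
#'   (and optionally `phase`) to scatter on top.
#' @param ... Passed on to [plot()].
#' @return Invisibly `NULL`.
#' @export
plot_qre <- function(trace, nash = TRUE, points = NULL, ...) {
  stopifnot(inherits(trace, "qre_trace"))
  plot(trace$alpha, trace$gamma, type = "p", pch = 16, cex = 0.4,
       col = "grey40", xlim = c(0, 1), ylim = c(0, 1),
       xlab = expression(alpha ~ "(tolerance to defection)"),
       ylab = expression(gamma ~ "(mutual cooperation)"), ...)
  if (nash) {
    nc <- nash_points(400)
    graphics::lines(nc$alpha, nc$gamma, lty = 2)
  }
  if (!is.null(points)) {
    col <- if ("phase" %in% names(points))
      ifelse(points$phase == "after", "violet", "orange") else "orange"
    graphics::points(points$alpha_hat, points$gamma_hat, pch = 17, col = col)
  }
  invisible(NULL)
}
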