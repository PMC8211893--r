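#' Plot a pointwise shape-statistics map on the template curve
#'
#' Draws the template outline colored by the inward-deformation effect
#' (`-beta_1`; warm colors = inward deformation in patients) and
#' highlights points whose FWER-corrected p-value is at or below
#' `alpha`.
#'
#' @param x a `cc_pointwise_stats`.
#' @param template the `cc_template` the statistics were computed on.
#' @param alpha highlight level (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.cc_pointwise_stats <- function(x, template, alpha = 0.05, ...) {
  pts <- template$points
  eff <- x$effect
  pal <- grDevices::colorRampPalette(c("navy", "grey85", "firebrick"))(101)
  rng <- max(abs(eff), 1e-12)
  col <- pal[round((eff / rng + 1) / 2 * 100) + 1]
  graphics::plot(rbind(pts, pts[1, ]), type = "l", col = "grey70",
                 asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = paste0("Inward deformation (-beta1), scope ",
                               x$scope), ...)
  graphics::points(pts, col = col, pch = 16, cex = 0.8)
  sig <- x$p_fwer <= alpha
  if (any(sig))
    graphics::points(pts[sig, , drop = FALSE], pch = 1, cex = 1.6,
                     lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("inward (FES)", "outward",
                              paste0("FWER p <= ", alpha)),
                   col = c("firebrick", "navy", "black"),
                   pch = c(16, 16, 1))
  invisible(x)
}
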