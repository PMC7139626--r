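# Figure-style views of the analysis objects (base graphics; optional).

#' Phase-plane view of the fixed-point structure
#'
#' Plots the fixed points in the H3K4me3-H3K27me3 plane on the non-linear
#' scale `x_k = 0.4 - 0.05 log10((m_max - m_k)/m_k)`; stable states are
#' filled, unstable ones open, labels annotated.
#'
#' @param x An `epi_fixed_points` table from [find_fixed_points()].
#' @param p The [epi_params()] the table was computed with.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_fixed_points <- function(x, p, ...) {
  x4 <- nonlinear_scale(pmax(x$m4, 1e-9), p$m4_max)
  x27 <- nonlinear_scale(pmax(x$m27, 1e-9), p$m27_max)
  graphics::plot(x4, x27, pch = ifelse(x$stable, 19, 1),
                 col = ifelse(x$stable, "red3", "black"),
                 xlab = "H3K4me3 (non-linear scale)",
                 ylab = "H3K27me3 (non-linear scale)", ...)
  graphics::text(x4, x27, x$label, pos = 4, cex = 0.8)
}

#' Occupancy histogram of a population run
#'
#' @param run An `epi_population` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot_occupancy <- function(run, ...) {
  h <- run$histogram
  mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  graphics::image(mids, mids, log10(1 + h$counts),
                  xlab = "m4", ylab = "m27",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
}

#' Branch diagram of a de novo methylation scan
#'
#' @param bif An `epi_bifurcation` object from [scan_bifurcation()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_bifurcation <- function(bif, ...) {
  b <- bif$branches
  graphics::plot(b$value, b$mcpg, pch = ifelse(b$stable, 19, 1),
                 col = ifelse(b$stable, "red3", "grey40"),
                 xlab = bif$param, ylab = "mcpg", ...)
  if (!is.null(bif$D_novo_C0) && !is.na(bif$D_novo_C0)) {
    graphics::abline(v = c(bif$D_novo_C0, bif$D_novo_C1), lty = 3)
  }
}
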