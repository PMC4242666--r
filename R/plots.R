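## Base-graphics views of the main objects.

#' @export
plot.casr_trace <- function(x, ...) {
  graphics::plot(x$time_s / 60, x$ratio, type = "l", xlab = "time (min)",
                 ylab = "340/380 ratio", main = x$cell_id, ...)
  graphics::abline(v = x$protocol$steps$start_s / 60, col = "grey80",
                   lty = 3)
  graphics::axis(3, at = (x$protocol$steps$start_s +
                            x$protocol$dwell_s / 2) / 60,
                 labels = x$protocol$steps$ca_mM, tick = FALSE,
                 cex.axis = 0.6, line = -1)
  invisible(x)
}

#' Plot a dose-response with its fitted curve
#'
#' @param dr a [dose_response()].
#' @param fit a `hill_fit` or `biphasic_fit` on those data (optional).
#' @param ... passed to [graphics::plot()].
#' @export
plot_dose_fit <- function(dr, fit = NULL, ...) {
  d <- dr$data
  graphics::plot(d$conc_mM, d$response, log = "x",
                 xlab = "concentration (mM)", ylab = dr$readout, ...)
  if (!is.null(fit)) {
    cc <- exp(seq(log(min(d$conc_mM)), log(max(d$conc_mM)), length.out = 200))
    graphics::lines(cc, stats::predict(fit, cc), col = "red3")
  }
  invisible(dr)
}

#' @export
plot.correlation_map <- function(x, residue_offset = 0, ...) {
  ## published map convention: blue = -1, green ~ 0, red = +1
  pal <- grDevices::colorRampPalette(c("blue", "green3", "red"))(101)
  n <- nrow(x$matrix)
  idx <- seq_len(n) + residue_offset
  graphics::image(idx, idx, t(x$matrix[n:1, , drop = FALSE])[, n:1],
                  zlim = c(-1, 1), col = pal, xlab = "residue",
                  ylab = "residue", ...)
  invisible(x)
}

#' @export
plot.traj_pca <- function(x, modes = c(1, 2), ...) {
  .assert(length(modes) == 2 && all(modes <= x$k), "invalid mode pair")
  graphics::plot(x$projections[, modes[1]], x$projections[, modes[2]],
                 xlab = sprintf("PC%d (%.0f%%)", modes[1],
                                100 * x$explained[modes[1]]),
                 ylab = sprintf("PC%d (%.0f%%)", modes[2],
                                100 * x$explained[modes[2]]),
                 pch = 16, cex = 0.4, col = "#00000044", ...)
  invisible(x)
}
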