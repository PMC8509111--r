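# RMSe-vs-height plots, one curve per target per solver mode.

#' Plot RMSe against scan height
#'
#' Draws the Monte Carlo RMSe curves of one scenario: one color per
#' target point, solid versus dashed lines distinguishing solver
#' modes when the scenario was run in more than one.
#'
#' @param tbl An RMSe table from [sweep_scenarios()] or
#'   [cmd_simulate()].
#' @param scenario Scenario id to plot; default the first in `tbl`.
#' @param main Plot title; default derived from the scenario.
#' @return Invisibly, the subset of `tbl` that was plotted.
#' @export
plot_rmse <- function(tbl, scenario = NULL, main = NULL) {
  stopifnot(is.data.frame(tbl), nrow(tbl) > 0)
  scenario <- scenario %||% tbl$scenario_id[1]
  d <- tbl[tbl$scenario_id == scenario, ]
  if (!nrow(d)) stop("no rows for scenario '", scenario, "'", call. = FALSE)
  targets <- unique(d$target)
  modes <- unique(d$mode)
  cols <- grDevices::hcl.colors(max(length(targets), 2), "Dark 2")
  graphics::plot(NA, xlim = range(d$z_mm), ylim = c(0, max(d$rmse_mm)),
                 xlab = "height z (mm)", ylab = "RMSe (mm)",
                 main = main %||% sprintf("%s: RMSe vs height", scenario))
  for (i in seq_along(targets)) for (j in seq_along(modes)) {
    dd <- d[d$target == targets[i] & d$mode == modes[j], ]
    dd <- dd[order(dd$z_mm), ]
    graphics::lines(dd$z_mm, dd$rmse_mm, col = cols[i], lty = j, lwd = 1.5)
  }
  graphics::legend("topright", bty = "n", cex = 0.8,
                   legend = c(targets, modes),
                   col = c(cols[seq_along(targets)],
                           rep("black", length(modes))),
                   lty = c(rep(1, length(targets)), seq_along(modes)))
  invisible(d)
}
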