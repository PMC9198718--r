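#' Diagnostic plots
#'
#' Base-graphics diagnostics: the steady-state I-V relationship, the Q-V
#' activation curve with its Boltzmann fit overlay, and the
#' current-fluorescence scatter with the slope-factor line.
#'
#' @param iv I-V table from [build_iv()].
#' @param fit Optional [fit_boltzmann()] result for the Q-V overlay.
#' @param main Plot title.
#' @return Invisibly, `NULL`; called for the plot side effect.
#' @export
plot_iv <- function(iv, main = "Steady-state I-V") {
  graphics::plot(iv$v, iv$i_ss, type = "b", pch = 16,
                 xlab = "Voltage (mV)", ylab = "Steady-state current (nA)",
                 main = main)
  graphics::abline(h = 0, col = "grey70")
  invisible(NULL)
}

#' @rdname plot_iv
#' @export
plot_qv <- function(iv, fit = NULL, main = "Q-V activation curve") {
  graphics::plot(iv$v, iv$q_off, pch = 16, xlab = "Prepulse voltage (mV)",
                 ylab = "Q_off (pC)", main = main)
  if (!is.null(fit)) {
    vv <- seq(min(iv$v), max(iv$v), length.out = 200)
    graphics::lines(vv, fit$predict(vv), col = "firebrick", lwd = 2)
    graphics::abline(v = fit$v_half, lty = 2, col = "firebrick")
  }
  invisible(NULL)
}

#' @rdname plot_iv
#' @param fluorescence,i_ss Per-cell values for the scatter.
#' @param slope A [fluorescence_slope()] result for the line overlay.
#' @export
plot_current_fluorescence <- function(fluorescence, i_ss, slope = NULL,
                                      main = "Current vs fluorescence") {
  graphics::plot(fluorescence, i_ss, pch = 16,
                 xlab = "Fluorescence (a.u.)", ylab = "Current (nA)",
                 main = main)
  if (!is.null(slope))
    graphics::abline(slope$intercept, slope$slope, col = "firebrick", lwd = 2)
  invisible(NULL)
}
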