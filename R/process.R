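#' P/8 leak subtraction
#'
#' Removes linear leak and linear capacitive transients from every test sweep
#' using the recorded P/8 subpulses. Each sweep (test and subpulse) is first
#' baseline-corrected by the mean of its pre-pulse segment; the averaged
#' subpulse response is then scaled by the sign-matched amplitude ratio
#' (test step / subpulse step, i.e. -8 or +8 for hyperpolarizing subpulses)
#' and subtracted sample-wise. Any current component linear in voltage
#' cancels exactly in the noise-free limit; nonlinear gating and transport
#' components are preserved.
#'
#' The returned recording keeps residual subpulses (each subpulse minus the
#' subpulse average), so that applying the subtraction a second time changes
#' the traces only by the noise floor.
#'
#' @param rec A `clc_recording`.
#' @return A `clc_recording` with `subtracted = TRUE` and provenance field
#'   `subtraction = "P/8"`.
#' @export
p8_subtract <- function(rec) {
  stopifnot(inherits(rec, "clc_recording"))
  p8 <- rec[["p8"]]
  if (is.null(p8) || length(p8) == 0)
    stop("recording has no P/8 subpulses")
  seg <- protocol_segments(rec$protocol)
  if (dim(p8)[1] != nrow(rec$sweeps))
    stop("subpulse and test sweeps have mismatched sample counts (dt)")
  if (dim(p8)[3] != ncol(rec$sweeps))
    stop("subpulse sweeps do not match the protocol voltages")
  volts <- protocol_voltages(rec$protocol)
  if (seg$n_pre < 1)
    stop("P/8 subtraction needs a pre-pulse baseline segment (pre_ms > 0)")

  out <- rec
  for (j in seq_along(volts)) {
    test <- rec$sweeps[, j]
    test <- test - mean(test[seg$idx_pre])
    subs <- p8[, , j, drop = FALSE][, , 1]
    sub_avg <- rowMeans(subs)
    sub_avg <- sub_avg - mean(sub_avg[seg$idx_pre])
    dv <- volts[j] - rec$protocol$holding
    amp <- rec$p8_amp[j]
    scale <- if (abs(amp) > 0) dv / amp else 0
    out$sweeps[, j] <- test - scale * sub_avg
    # residual subpulses: each minus the common average (pure noise if the
    # subpulse response was linear)
    resid <- subs - rowMeans(subs)
    resid <- sweep(resid, 2, colMeans(resid[seg$idx_pre, , drop = FALSE]))
    out$p8[, , j] <- resid
    out$p8_amp[j] <- amp
  }
  out$subtracted <- TRUE
  out$subtraction <- "P/8"
  out
}

#' Steady-state current per test voltage
#'
#' Mean current over a window at the end of the test pulse, per voltage.
#' The default window is the last 2 ms of the pulse, by which time the
#' simulated activation gate (tau ~ 0.5 ms at positive voltages) has settled.
#'
#' @param rec A `clc_recording` (normally P/8 subtracted).
#' @param window_ms Length-2 interval in ms relative to pulse onset; must lie
#'   inside the pulse and have positive length. Default: last 2 ms.
#' @return Data frame with columns `v` (mV) and `i_ss` (nA), ascending in `v`.
#' @export
measure_steady_state <- function(rec, window_ms = NULL) {
  stopifnot(inherits(rec, "clc_recording"))
  pr <- rec$protocol
  if (is.null(window_ms)) window_ms <- c(pr$pulse_ms - 2, pr$pulse_ms)
  if (length(window_ms) != 2 || diff(window_ms) <= 0)
    stop("window_ms must be an interval of positive length")
  if (window_ms[1] < 0 || window_ms[2] > pr$pulse_ms)
    stop("steady-state window must lie inside the test pulse")
  seg <- protocol_segments(rec$protocol)
  keep <- seg$t_pulse >= window_ms[1] & seg$t_pulse <= window_ms[2]
  if (!any(keep)) stop("steady-state window contains no samples")
  i_ss <- colMeans(rec$sweeps[seg$idx_pulse, , drop = FALSE][keep, , drop = FALSE]) / 1000
  data.frame(v = protocol_voltages(pr), i_ss = i_ss)
}

#' Integrated off-gating charge per prepulse
#'
#' Integrates the tail current recorded at the holding potential after each
#' test (pre)pulse. A baseline estimated from the final `baseline_frac` of
#' the tail is subtracted, then the trace is integrated by the trapezoidal
#' rule at native sampling over `tail_window_ms`. The default window starts
#' at repolarization (0 ms): after P/8 subtraction the linear capacitance
#' transient cancels, so no guard interval is needed.
#'
#' Sign convention: with `signed = FALSE` (default) the positive magnitude of
#' the integrated charge is returned. With `signed = TRUE` the charge is
#' reported as positive when the tail current is inward (negative) at
#' holding, i.e. positive Q_off corresponds to gating charge returning after
#' a depolarizing prepulse; hyperpolarizing prepulses can then yield negative
#' values. The Q-V analysis uses the signed convention.
#'
#' @param rec A `clc_recording` (normally P/8 subtracted).
#' @param tail_window_ms Length-2 integration interval in ms after
#'   repolarization; must fit inside the recorded tail.
#' @param baseline_frac Fraction of the tail end used for the baseline
#'   estimate (default: the second half of the tail, which starts more than
#'   15 off-relaxation time constants after repolarization; the longer
#'   window halves the baseline-noise contribution to the charge).
#' @param signed Return the inward-positive signed charge instead of the
#'   magnitude.
#' @return Data frame with columns `v` (prepulse, mV) and `q_off` (pC).
#' @export
integrate_qoff <- function(rec, tail_window_ms = c(0, 10),
                           baseline_frac = 0.5, signed = FALSE) {
  stopifnot(inherits(rec, "clc_recording"))
  pr <- rec$protocol
  if (length(tail_window_ms) != 2 || diff(tail_window_ms) <= 0)
    stop("tail_window_ms must be an interval of positive length")
  if (tail_window_ms[2] > pr$tail_ms)
    stop("tail is shorter than the integration window")
  seg <- protocol_segments(rec$protocol)
  n_tail <- seg$n_tail
  n_base <- max(1, round(baseline_frac * n_tail))
  keep <- seg$t_tail >= tail_window_ms[1] & seg$t_tail <= tail_window_ms[2]
  if (sum(keep) < 2) stop("integration window contains fewer than 2 samples")
  tk <- seg$t_tail[keep]

  q <- apply(rec$sweeps[seg$idx_tail, , drop = FALSE], 2, function(tail) {
    base <- mean(tail[(n_tail - n_base + 1):n_tail])
    x <- tail[keep] - base
    trapz(tk, x) / 1000  # pA*ms -> pC
  })
  if (!signed) q <- abs(q) else q <- -q
  data.frame(v = protocol_voltages(pr), q_off = q)
}

# trapezoidal integral on an ordered grid
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Assemble the per-voltage I-V / Q-V table of one cell
#'
#' Runs [measure_steady_state()] and [integrate_qoff()] (signed convention)
#' on a leak-subtracted recording and returns one row per protocol voltage,
#' sorted ascending.
#'
#' @param rec A `clc_recording`; if not yet subtracted, [p8_subtract()] is
#'   applied first.
#' @param window_ms,tail_window_ms,baseline_frac Passed through.
#' @return Data frame with columns `v` (mV), `i_ss` (nA), `q_off` (pC).
#' @export
build_iv <- function(rec, window_ms = NULL, tail_window_ms = c(0, 10),
                     baseline_frac = 0.5) {
  if (!isTRUE(rec$subtracted)) rec <- p8_subtract(rec)
  iv <- measure_steady_state(rec, window_ms)
  qv <- integrate_qoff(rec, tail_window_ms, baseline_frac, signed = TRUE)
  out <- merge(iv, qv, by = "v")
  out[order(out$v), , drop = FALSE]
}
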