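#' Voltage-step protocol specification
#'
#' Describes the whole-cell stimulation protocol used throughout the package:
#' square test pulses from a holding potential, followed by a tail recording
#' back at holding, with P/8 leak subpulses delivered from a separate baseline
#' potential. The defaults reproduce the study protocol: 10 ms pulses from
#' -115 to +175 mV in 10 mV increments from a 0 mV holding potential, sampled
#' at 100 kHz, with P/8 subpulses from a -30 mV baseline.
#'
#' @param holding Holding potential (mV). Test sweeps rest and return here.
#' @param v_start,v_end,v_step Test-pulse voltage grid (mV); `v_end - v_start`
#'   must be divisible by `v_step`.
#' @param pulse_ms Test-pulse duration (ms).
#' @param interval_ms Inter-sweep interval (ms); long enough that the cell
#'   re-equilibrates at `holding` between sweeps (not explicitly sampled).
#' @param sample_khz Sampling rate (kHz); every segment duration times
#'   `sample_khz` must give an integer sample count.
#' @param tail_ms Post-pulse recording at holding (ms). The off-gating charge
#'   is integrated over this segment.
#' @param pre_ms Pre-pulse baseline recording at the sweep's resting potential
#'   (ms); used for per-sweep baseline correction.
#' @param p8_baseline Baseline potential (mV) from which leak subpulses are
#'   delivered.
#' @param p8_count Number of leak subpulses per test voltage (the "8" in P/8).
#'
#' @return An object of class `clc_protocol`.
#' @examples
#' p <- protocol_spec()
#' protocol_voltages(p)
#' @export
protocol_spec <- function(holding = 0, v_start = -115, v_end = 175,
                          v_step = 10, pulse_ms = 10, interval_ms = 500,
                          sample_khz = 100, tail_ms = 20, pre_ms = 2,
                          p8_baseline = -30, p8_count = 8) {
  if (v_step <= 0) stop("v_step must be positive")
  if (v_end < v_start) stop("v_end must not be below v_start")
  if (abs(((v_end - v_start) / v_step) %% 1) > 1e-9)
    stop("(v_end - v_start) must be divisible by v_step")
  if (sample_khz <= 0 || pulse_ms <= 0 || tail_ms <= 0 || pre_ms < 0)
    stop("sampling and segment durations must be positive")
  for (seg in c(pre_ms, pulse_ms, tail_ms)) {
    n <- seg * sample_khz
    if (abs(n - round(n)) > 1e-9)
      stop("segment duration times sample_khz must give an integer sample count")
  }
  if (p8_count < 1) stop("p8_count must be at least 1")
  structure(list(holding = holding, v_start = v_start, v_end = v_end,
                 v_step = v_step, pulse_ms = pulse_ms,
                 interval_ms = interval_ms, sample_khz = sample_khz,
                 tail_ms = tail_ms, pre_ms = pre_ms,
                 p8_baseline = p8_baseline, p8_count = p8_count),
            class = "clc_protocol")
}

#' Test voltages of a protocol
#' @param protocol A [protocol_spec()] object.
#' @return Numeric vector of test-pulse voltages (mV), ascending.
#' @export
protocol_voltages <- function(protocol) {
  seq(protocol$v_start, protocol$v_end, by = protocol$v_step)
}

# Sample counts and per-segment time vectors (ms, t = 0 at segment start).
# Samples are taken at the start of each dt interval; the last sample of a
# segment falls dt before the next segment begins.
protocol_segments <- function(protocol) {
  dt <- 1 / protocol$sample_khz
  n_pre <- round(protocol$pre_ms * protocol$sample_khz)
  n_pulse <- round(protocol$pulse_ms * protocol$sample_khz)
  n_tail <- round(protocol$tail_ms * protocol$sample_khz)
  list(dt = dt, n_pre = n_pre, n_pulse = n_pulse, n_tail = n_tail,
       n_total = n_pre + n_pulse + n_tail,
       idx_pre = seq_len(n_pre),
       idx_pulse = n_pre + seq_len(n_pulse),
       idx_tail = n_pre + n_pulse + seq_len(n_tail),
       t_pre = (seq_len(n_pre) - 1) * dt,
       t_pulse = (seq_len(n_pulse) - 1) * dt,
       t_tail = (seq_len(n_tail) - 1) * dt)
}

#' @export
print.clc_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage-step protocol: %g..%g mV by %g mV (holding %g mV)\n",
    x$v_start, x$v_end, x$v_step, x$holding))
  cat(sprintf("  pulse %g ms, tail %g ms, pre %g ms, sampled at %g kHz\n",
              x$pulse_ms, x$tail_ms, x$pre_ms, x$sample_khz))
  cat(sprintf("  P/%d leak subpulses from %g mV baseline\n",
              x$p8_count, x$p8_baseline))
  invisible(x)
}
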