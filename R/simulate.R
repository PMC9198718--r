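#' Simulate one whole-cell recording
#'
#' Generates the full sweep set of one simulated cell under a voltage-step
#' protocol: for every test voltage a pre/pulse/tail sweep containing the
#' transporter's activation-gated, outwardly rectifying transport current,
#' on/off gating (capacitive) currents carried by the gate's charge movement,
#' linear leak, a membrane-capacitance transient charged through the residual
#' series resistance, and white Gaussian noise; plus the P/8 leak subpulses
#' delivered hyperpolarizing from the `p8_baseline` potential. Expression
#' level is drawn lognormally per cell and linked to a fluorescence value
#' `fluor_gain * expr_scale * cell_factor + fluor_bg`.
#'
#' The gate relaxes exponentially toward
#' `pinf(V) = 1/(1 + exp(-(V - v_half)/k_slope))` with a voltage-dependent
#' time constant `tau_gate()`: about 0.5 ms at and above 0 mV (so the 10 ms
#' pulse reaches steady state and the 20 ms tail captures > 99.9% of the
#' off charge) and effectively frozen below about -30 mV, which keeps gating
#' charge immobile during the P/8 subpulses. The transport current at a
#' voltage `V != holding` is `I_max * p(t) * r(V)`; at the holding potential
#' it is zero (holding sits at the anion reversal potential under the
#' near-symmetric chloride solutions emulated here). Gating current is
#' `Q_max * dp/dt`, so on- and off-gating charge are conservative by
#' construction; `Q_max` is scaled so that `Q_off/I_ss` at the variant's
#' reference prepulse equals `rho_ref`.
#'
#' All per-cell ground truth (expression factor, `I_max`, `Q_max`,
#' fluorescence, model parameters) is stored alongside the traces, together
#' with the noise-free nonlinear (gating + transport) component of every test
#' sweep when `store_components = TRUE`.
#'
#' @param variant A [variant_config()].
#' @param protocol A [protocol_spec()].
#' @param passive A [cell_passive_spec()].
#' @param seed Integer seed; fixes the expression draw and all noise.
#' @param cell_id Cell identifier stored in the metadata.
#' @param store_components Keep the noise-free nonlinear component of each
#'   test sweep (used by oracle tests)?
#'
#' @return An object of class `clc_recording` with elements `sweeps`
#'   (samples x voltages matrix, pA), `p8` (samples x subpulses x voltages
#'   array), `p8_amp` (subpulse amplitude per test voltage, mV),
#'   `fluorescence`, `truth`, `components`, `meta`, `protocol`, `variant`,
#'   `passive`.
#' @export
simulate_cell <- function(variant, protocol = protocol_spec(),
                          passive = cell_passive_spec(), seed = 1,
                          cell_id = "cell_01", store_components = TRUE) {
  stopifnot(inherits(variant, "clc_variant"), inherits(protocol, "clc_protocol"),
            inherits(passive, "clc_passive"))
  if (variant$k_slope <= 0) stop("k_slope must be positive")
  set.seed(seed)
  seg <- protocol_segments(protocol)
  volts <- protocol_voltages(protocol)
  nv <- length(volts)

  cell_factor <- exp(stats::rnorm(1, 0, passive$sigma_ln))
  i_max <- variant$i_max_density * variant$expr_scale *
    variant$surface_fraction * cell_factor
  p0 <- pinf(protocol$holding, variant$v_half, variant$k_slope)
  dp_ref <- pinf(variant$v_ref, variant$v_half, variant$k_slope) - p0
  if (dp_ref <= 0)
    stop("reference prepulse must move the activation gate (v_ref above holding)")
  i_ss_ref <- i_max * pinf(variant$v_ref, variant$v_half, variant$k_slope) *
    rectifier(variant$v_ref, variant$rect_v)
  q_max <- variant$rho_ref * i_ss_ref / dp_ref
  fluor <- passive$fluor_gain * variant$expr_scale * cell_factor +
    passive$fluor_bg

  sweeps <- matrix(0, seg$n_total, nv)
  components <- if (store_components) matrix(0, seg$n_total, nv) else NULL
  p8 <- array(0, c(seg$n_total, protocol$p8_count, nv))
  p8_amp <- numeric(nv)

  for (j in seq_len(nv)) {
    sw <- synth_sweep(protocol$holding, volts[j], variant, i_max, q_max,
                      passive, protocol, seg)
    noise <- if (passive$noise_sd > 0)
      stats::rnorm(seg$n_total, 0, passive$noise_sd) else 0
    sweeps[, j] <- sw$total + noise
    if (store_components) components[, j] <- sw$nonlinear

    dv <- volts[j] - protocol$holding
    amp <- -abs(dv) / protocol$p8_count
    p8_amp[j] <- amp
    sub <- synth_sweep(protocol$p8_baseline, protocol$p8_baseline + amp,
                       variant, i_max, q_max, passive, protocol, seg)
    for (k in seq_len(protocol$p8_count)) {
      noise <- if (passive$noise_sd > 0)
        stats::rnorm(seg$n_total, 0, passive$noise_sd) else 0
      p8[, k, j] <- sub$total + noise
    }
  }

  structure(list(
    protocol = protocol, variant = variant, passive = passive,
    sweeps = sweeps, p8 = p8, p8_amp = p8_amp, fluorescence = fluor,
    components = components,
    truth = list(cell_factor = cell_factor, i_max = i_max, q_max = q_max,
                 fluorescence = fluor, v_half = variant$v_half,
                 k_slope = variant$k_slope, rho_ref = variant$rho_ref,
                 v_ref = variant$v_ref, rect_v = variant$rect_v,
                 p_holding = p0),
    meta = list(cell_id = cell_id, variant = variant$name, seed = seed),
    subtracted = FALSE), class = "clc_recording")
}

# One noise-free sweep: pre at v_rest, pulse at v_pulse, tail at v_rest.
# Currents in pA. Returns the total and its nonlinear (gating + transport,
# baseline-relative) component.
synth_sweep <- function(v_rest, v_pulse, variant, i_max, q_max, passive,
                        protocol, seg) {
  p_rest <- pinf(v_rest, variant$v_half, variant$k_slope)
  pinf_p <- pinf(v_pulse, variant$v_half, variant$k_slope)
  tau_p <- tau_gate(v_pulse)
  tau_t <- tau_gate(v_rest)

  # gate trajectory (continuous-time endpoints, sampled on the grid)
  p_pulse <- pinf_p + (p_rest - pinf_p) * exp(-seg$t_pulse / tau_p)
  p_end <- pinf_p + (p_rest - pinf_p) * exp(-protocol$pulse_ms / tau_p)
  p_tail <- p_rest + (p_end - p_rest) * exp(-seg$t_tail / tau_t)

  # gating current Q_max * dp/dt (pC/ms = nA -> pA)
  ig_pulse <- 1000 * q_max * (pinf_p - p_rest) / tau_p * exp(-seg$t_pulse / tau_p)
  ig_tail <- 1000 * q_max * (p_rest - p_end) / tau_t * exp(-seg$t_tail / tau_t)

  # transport current; zero at the holding (reversal) potential
  tr_at <- function(p, v) {
    if (v == protocol$holding) rep(0, length(p))
    else 1000 * i_max * p * rectifier(v, variant$rect_v)
  }
  itr_pre <- tr_at(rep(p_rest, seg$n_pre), v_rest)
  itr_pulse <- tr_at(p_pulse, v_pulse)
  itr_tail <- tr_at(p_tail, v_rest)

  # linear leak (nS * mV = pA)
  leak <- c(rep(passive$g_leak * v_rest, seg$n_pre),
            rep(passive$g_leak * v_pulse, seg$n_pulse),
            rep(passive$g_leak * v_rest, seg$n_tail))

  # membrane-capacitance transient through residual series resistance
  cap <- numeric(seg$n_total)
  if (passive$r_s > 0 && passive$c_m > 0) {
    tau_c <- passive$r_s * passive$c_m / 1000  # MOhm * pF = us -> ms
    dv <- v_pulse - v_rest
    cap[seg$idx_pulse] <- 1000 * dv / passive$r_s * exp(-seg$t_pulse / tau_c)
    cap[seg$idx_tail] <- -1000 * dv / passive$r_s * exp(-seg$t_tail / tau_c)
  }

  gating <- c(rep(0, seg$n_pre), ig_pulse, ig_tail)
  transport <- c(itr_pre, itr_pulse, itr_tail)
  nl_rest <- if (v_rest == protocol$holding) 0
             else 1000 * i_max * p_rest * rectifier(v_rest, variant$rect_v)
  list(total = leak + cap + gating + transport,
       nonlinear = gating + transport - nl_rest)
}

#' Simulate a cohort of cells
#'
#' One [simulate_cell()] per cell with per-cell seeds derived
#' deterministically from the cohort seed, plus a manifest collecting the
#' per-cell ground truth.
#'
#' @param variants A [variant_config()] or list of them.
#' @param n_cells_per_variant Integer (recycled across variants); must be >= 1.
#' @param protocol,passive See [simulate_cell()].
#' @param seed Cohort seed; the same seed reproduces the cohort exactly.
#' @param store_components Passed to [simulate_cell()] (default off to bound
#'   memory).
#' @return An object of class `clc_cohort`: list of recordings in `$cells`
#'   and a data frame `$manifest` (cell_id, variant, fluorescence, seed and
#'   ground-truth columns).
#' @export
simulate_cohort <- function(variants, n_cells_per_variant,
                            protocol = protocol_spec(),
                            passive = cell_passive_spec(), seed = 1,
                            store_components = FALSE) {
  if (inherits(variants, "clc_variant")) variants <- list(variants)
  if (length(variants) == 0) stop("variant list must not be empty")
  if (any(n_cells_per_variant < 1)) stop("n_cells_per_variant must be >= 1")
  n <- rep_len(n_cells_per_variant, length(variants))
  set.seed(seed)
  cell_seeds <- sample.int(2147483646L, sum(n))

  cells <- vector("list", sum(n))
  rows <- vector("list", sum(n))
  idx <- 0
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    for (ci in seq_len(n[i])) {
      idx <- idx + 1
      id <- sprintf("%s_%02d", v$name, ci)
      rec <- simulate_cell(v, protocol, passive, seed = cell_seeds[idx],
                           cell_id = id, store_components = store_components)
      cells[[idx]] <- rec
      rows[[idx]] <- data.frame(
        cell_id = id, variant = v$name, fluorescence = rec$fluorescence,
        cell_factor = rec$truth$cell_factor, i_max = rec$truth$i_max,
        q_max = rec$truth$q_max, v_half = v$v_half, k_slope = v$k_slope,
        rho_ref = v$rho_ref, v_ref = v$v_ref, seed = cell_seeds[idx],
        stringsAsFactors = FALSE)
    }
  }
  names(cells) <- vapply(cells, function(r) r$meta$cell_id, "")
  structure(list(cells = cells, manifest = do.call(rbind, rows),
                 protocol = protocol, passive = passive, seed = seed),
            class = "clc_cohort")
}

#' @export
print.clc_recording <- function(x, ...) {
  cat(sprintf("Whole-cell recording %s (%s): %d test sweeps, %d samples each\n",
              x$meta$cell_id, x$meta$variant, ncol(x$sweeps), nrow(x$sweeps)))
  cat(sprintf("  fluorescence %.1f a.u.; %s\n", x$fluorescence,
              if (x$subtracted) "P/8 subtracted" else "raw"))
  invisible(x)
}

#' @export
print.clc_cohort <- function(x, ...) {
  tab <- table(x$manifest$variant)
  cat(sprintf("Simulated cohort: %d cells (%s)\n", nrow(x$manifest),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}
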