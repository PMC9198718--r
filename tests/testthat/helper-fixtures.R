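# Shared fixtures: reduced-sampling protocols keep unit tests fast while
# preserving every timing relationship of the full protocol; the acceptance
# tests use the full 100 kHz protocol.

fast_protocol <- function(sample_khz = 20, ...) {
  protocol_spec(sample_khz = sample_khz, ...)
}

quiet_passive <- function(...) {
  cell_passive_spec(noise_sd = 0, sigma_ln = 0, ...)
}

# reduced-sampling equivalent of the default recording noise: white noise of
# fixed spectral density has per-sample sd proportional to 1/sqrt(dt)
scaled_passive <- function(sample_khz, ...) {
  cell_passive_spec(noise_sd = 15 * sqrt(sample_khz / 100), ...)
}

wt_variant <- function(...) {
  variant_config("WT", v_half = 75, ...)
}

# a purely passive cell: no transporter at all
passive_only_variant <- function() {
  variant_config("passive", v_half = 75, rho_ref = 1e-9,
                 surface_fraction = 0)
}

# closed-form steady-state transport current (nA) from stored ground truth
true_iss <- function(truth, v) {
  truth$i_max * pinf(v, truth$v_half, truth$k_slope) *
    rectifier(v, truth$rect_v)
}

# closed-form off charge (pC) after full equilibration at prepulse v
true_qoff <- function(truth, v, holding = 0) {
  truth$q_max * (pinf(v, truth$v_half, truth$k_slope) -
                 pinf(holding, truth$v_half, truth$k_slope))
}

# dense grid-search oracle for the Boltzmann fit: q_max solved linearly for
# each (v_half, k) grid node (conditionally linear model)
grid_boltzmann_sse <- function(v, q, v_half_grid, k_grid, holding = NULL) {
  best <- Inf
  for (vh in v_half_grid) for (k in k_grid) {
    s <- 1 / (1 + exp(-(v - vh) / k))
    if (!is.null(holding)) s <- s - 1 / (1 + exp(-(holding - vh) / k))
    qm <- sum(q * s) / sum(s^2)
    qm <- max(qm, 0)
    sse <- sum((q - qm * s)^2)
    if (sse < best) best <- sse
  }
  best
}
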