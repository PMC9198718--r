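test_that("noise-free simulation is a closed-form object", {
  pr <- fast_protocol()
  seg <- clc4quant:::protocol_segments(pr)
  # no noise, no leak, no capacitance: steady current at v_half is half the
  # rectified maximum
  v <- wt_variant()
  pas <- quiet_passive(g_leak = 0, c_m = 0)
  rec <- simulate_cell(v, pr, pas, seed = 1)
  tr <- rec$truth
  j <- which(protocol_voltages(pr) == 75)
  i_end <- rec$sweeps[max(seg$idx_pulse), j] / 1000
  expect_equal(i_end, 0.5 * tr$i_max * rectifier(75, v$rect_v),
               tolerance = 1e-6)
  # fluorescence follows its defining formula exactly
  pasf <- cell_passive_spec(noise_sd = 0)
  recf <- simulate_cell(v, pr, pasf, seed = 7)
  expect_equal(recf$fluorescence,
               pasf$fluor_gain * v$expr_scale * recf$truth$cell_factor +
                 pasf$fluor_bg)
})

test_that("currents at strongly negative voltages are leak only", {
  pr <- fast_protocol()
  pas <- cell_passive_spec(sigma_ln = 0)  # noisy, leak 1 nS
  rec <- simulate_cell(wt_variant(), pr, pas, seed = 3)
  seg <- clc4quant:::protocol_segments(pr)
  j <- which(protocol_voltages(pr) == -115)
  late <- rec$sweeps[rev(seg$idx_pulse)[1:20], j]
  # raw steady current within noise of g_leak * (-115 mV)
  expect_lt(abs(mean(late) - pas$g_leak * (-115)),
            4 * pas$noise_sd / sqrt(20))
})

test_that("off-gating charge is monotone in prepulse and saturates", {
  pr <- fast_protocol()
  rec <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 1)
  qv <- integrate_qoff(p8_subtract(rec), signed = TRUE)
  above <- qv$v >= -5  # gate mobile range
  expect_true(all(diff(qv$q_off[above]) > -1e-6))
  q_sat <- rec$truth$q_max * (1 - pinf(0, 75, 25))
  expect_lt(max(qv$q_off), q_sat + 1e-9)
  expect_equal(max(qv$q_off),
               rec$truth$q_max * (pinf(175, 75, 25) - pinf(0, 75, 25)),
               tolerance = 0.01)
})

test_that("full pipeline round-trips the configured Q_off/current ratio", {
  pr <- fast_protocol()
  for (vc in list(wt_variant(), clc4_variants("chimera")$L221V_chimera)) {
    rec <- simulate_cell(vc, pr, quiet_passive(), seed = 5)
    m <- analyze_recording(rec)$metrics
    expect_equal(m$rho, vc$rho_ref, tolerance = 0.01)
    expect_equal(m$v_half, vc$v_half, tolerance = 0.05)
    expect_equal(m$k, vc$k_slope, tolerance = 0.1)
  }
})

test_that("cohorts are deterministic in the seed with shared ground truth", {
  pr <- fast_protocol(sample_khz = 10)
  v <- wt_variant()
  co1 <- simulate_cohort(v, 3, pr, cell_passive_spec(), seed = 42)
  co2 <- simulate_cohort(v, 3, pr, cell_passive_spec(), seed = 42)
  expect_identical(co1$cells[[2]]$sweeps, co2$cells[[2]]$sweeps)
  expect_identical(co1$manifest, co2$manifest)
  co3 <- simulate_cohort(v, 3, pr, cell_passive_spec(), seed = 43)
  expect_false(identical(co1$cells[[1]]$sweeps, co3$cells[[1]]$sweeps))
  expect_error(simulate_cohort(v, 0, pr), "n_cells_per_variant")
  expect_error(simulate_cohort(list(), 3, pr), "empty")
})

test_that("simulation rejects invalid specifications", {
  pr <- fast_protocol()
  bad <- wt_variant()
  bad$k_slope <- -5
  expect_error(simulate_cell(bad, pr, quiet_passive()), "k_slope")
})
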