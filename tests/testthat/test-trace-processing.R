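test_that("P/8 subtraction removes linear components exactly when noise-free", {
  pr <- fast_protocol()
  rec <- simulate_cell(passive_only_variant(), pr, quiet_passive(), seed = 1)
  sub <- p8_subtract(rec)
  expect_lt(max(abs(sub$sweeps)), 1e-9)
  expect_true(sub$subtracted)
  expect_identical(sub$subtraction, "P/8")
})

test_that("P/8 subtraction leaves zero-mean noise on noisy passive cells", {
  pr <- fast_protocol(sample_khz = 10)
  pas <- cell_passive_spec(sigma_ln = 0)
  rec <- simulate_cell(passive_only_variant(), pr, pas, seed = 2)
  sub <- p8_subtract(rec)
  # subtracted noise has sd ~ sqrt(1 + 64/8) * noise_sd = 3 * noise_sd;
  # per-sweep baseline correction adds a small common offset per sweep
  expect_lt(abs(mean(sub$sweeps)), 6)
  expect_equal(stats::sd(as.vector(sub$sweeps)), 3 * pas$noise_sd,
               tolerance = 0.06)
})

test_that("subtraction preserves the stored nonlinear component", {
  pr <- fast_protocol()
  pas <- cell_passive_spec(sigma_ln = 0, noise_sd = 10)
  rec <- simulate_cell(wt_variant(), pr, pas, seed = 4,
                       store_components = TRUE)
  sub <- p8_subtract(rec)
  resid <- sub$sweeps - rec$components
  # residual is the (3x) subtraction noise: bounded at 3 effective sd for
  # almost every sample, with matching rms
  expect_gt(mean(abs(resid) < 3 * 3 * pas$noise_sd), 0.997)
  expect_lt(sqrt(mean(resid^2)), 3.3 * pas$noise_sd)
  # noise-free limit: residual is the negligible subpulse-transport
  # contamination, far below the nonlinear signal itself
  rec0 <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 4,
                        store_components = TRUE)
  sub0 <- p8_subtract(rec0)
  expect_lt(max(abs(sub0$sweeps - rec0$components)),
            0.005 * max(abs(rec0$components)))
})

test_that("applying P/8 subtraction twice changes traces only by the noise floor", {
  pr <- fast_protocol(sample_khz = 10)
  pas <- cell_passive_spec(sigma_ln = 0)
  rec <- simulate_cell(wt_variant(), pr, pas, seed = 6)
  s1 <- p8_subtract(rec)
  s2 <- p8_subtract(s1)
  delta <- s2$sweeps - s1$sweeps
  # second pass subtracts scaled residual subpulse noise only
  expect_lt(stats::sd(as.vector(delta)), 3.5 * pas$noise_sd)
  expect_lt(abs(mean(delta)), 0.5)
})

test_that("subtraction validates its inputs", {
  pr <- fast_protocol(sample_khz = 10)
  rec <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 1)
  rec$p8 <- NULL
  expect_error(p8_subtract(rec), "no P/8")
  rec2 <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 1)
  rec2$p8 <- rec2$p8[1:10, , , drop = FALSE]
  expect_error(p8_subtract(rec2), "mismatched")
})

test_that("steady-state measurement is the windowed mean", {
  pr <- fast_protocol()
  rec <- simulate_cell(passive_only_variant(), pr, quiet_passive(), seed = 1)
  # constant 1 nA during the pulse
  seg <- clc4quant:::protocol_segments(pr)
  rec$sweeps[seg$idx_pulse, ] <- 1000
  rec$subtracted <- TRUE
  iss <- measure_steady_state(rec)
  expect_equal(iss$i_ss, rep(1, nrow(iss)))
  expect_error(measure_steady_state(rec, c(5, 5)), "positive length")
  expect_error(measure_steady_state(rec, c(8, 12)), "inside the test pulse")
})

test_that("steady state matches the closed form on noise-free cells", {
  pr <- fast_protocol()
  rec <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 2)
  iss <- measure_steady_state(p8_subtract(rec))
  j <- which(iss$v == 175)
  expect_equal(iss$i_ss[j], true_iss(rec$truth, 175), tolerance = 0.005)
})

test_that("off-charge integration matches the analytic exponential", {
  pr <- fast_protocol()
  seg <- clc4quant:::protocol_segments(pr)
  rec <- simulate_cell(passive_only_variant(), pr, quiet_passive(), seed = 1)
  rec$sweeps[] <- 0
  rec$subtracted <- TRUE
  # zero trace -> zero charge
  expect_equal(integrate_qoff(rec)$q_off, rep(0, 30))
  # synthetic tail 100 pA * exp(-t / 1 ms) -> 0.1 pC over a long window
  rec$sweeps[seg$idx_tail, 1] <- 100 * exp(-seg$t_tail / 1)
  q <- integrate_qoff(rec, tail_window_ms = c(0, 20))$q_off[1]
  expect_equal(q, 0.1, tolerance = 0.01)
  # linearity: scaling the tail scales the charge
  rec2 <- rec
  rec2$sweeps[seg$idx_tail, 1] <- 3.7 * rec$sweeps[seg$idx_tail, 1]
  expect_equal(integrate_qoff(rec2, c(0, 20))$q_off[1], 3.7 * q,
               tolerance = 1e-9)
  expect_error(integrate_qoff(rec, c(0, 50)), "shorter")
})

test_that("processed Q_off matches the simulator's charge curve", {
  pr <- fast_protocol()
  rec <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 3)
  qv <- integrate_qoff(p8_subtract(rec), signed = TRUE)
  for (vp in c(55, 95, 135, 175)) {
    j <- which(qv$v == vp)
    expect_equal(qv$q_off[j], true_qoff(rec$truth, vp), tolerance = 0.01)
  }
})

test_that("build_iv returns one sorted point per protocol voltage", {
  pr <- fast_protocol()
  rec <- simulate_cell(wt_variant(), pr, quiet_passive(), seed = 1)
  iv <- build_iv(rec)
  expect_equal(nrow(iv), 30)
  expect_true(all(diff(iv$v) > 0))
  expect_named(iv, c("v", "i_ss", "q_off"))
  pr1 <- fast_protocol(v_start = 135, v_end = 135, v_step = 10)
  rec1 <- simulate_cell(wt_variant(), pr1, quiet_passive(), seed = 1)
  expect_equal(nrow(build_iv(rec1)), 1)
})
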