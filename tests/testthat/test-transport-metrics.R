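test_that("Q_off/current ratio is the defining quotient with a noise gate", {
  expect_equal(as.numeric(qoff_current_ratio(0.2, 2)), 0.1)
  r <- qoff_current_ratio(0.2, 0.01)
  expect_true(is.na(r))
  expect_false(attr(r, "defined"))
})

test_that("transport activity obeys its defining identities", {
  nq <- data.frame(v = c(55, 95, 135), q_norm = c(0.3, 0.8, 0.95))
  ta <- transport_activity(nq, rho = 0.1)
  expect_equal(ta$ta, nq$q_norm / 0.1)
  # rho = 1 is the identity
  expect_equal(transport_activity(nq, 1)$ta, nq$q_norm)
  # doubling rho halves the curve everywhere
  expect_equal(transport_activity(nq, 0.2)$ta, ta$ta / 2)
  # low normalized charge is masked
  nq2 <- data.frame(v = c(-15, 135), q_norm = c(0.01, 0.9))
  expect_true(is.na(transport_activity(nq2, 0.1)$ta[1]))
  # undefined rho propagates as flagged missing
  ta_na <- transport_activity(nq, NA_real_)
  expect_true(all(is.na(ta_na$ta)))
  expect_false(attr(ta_na, "defined"))
})

test_that("transport activity of simulated variants scales inversely with rho", {
  pr <- fast_protocol()
  v1 <- wt_variant()
  v2 <- wt_variant(rho_ref = 2 * v1$rho_ref)  # equal activation, 2x rho
  a1 <- analyze_recording(simulate_cell(v1, pr, quiet_passive(), seed = 9))
  a2 <- analyze_recording(simulate_cell(v2, pr, quiet_passive(), seed = 9))
  keep <- !is.na(a1$ta$ta) & !is.na(a2$ta$ta)
  expect_gt(sum(keep), 5)
  expect_equal(a1$ta$ta[keep], 2 * a2$ta$ta[keep], tolerance = 0.01)
})

test_that("slope factor matches the closed-form normal equations", {
  # exact line through the origin
  s <- fluorescence_slope(c(1, 2, 3), c(2, 4, 6))
  expect_equal(s$slope, 2)
  expect_equal(s$intercept, 0, tolerance = 1e-12)
  # arbitrary points against the hand oracle
  f <- c(10, 35, 80)
  i <- c(0.5, 2.1, 3.2)
  beta <- sum((f - mean(f)) * (i - mean(i))) / sum((f - mean(f))^2)
  alpha <- mean(i) - beta * mean(f)
  s2 <- fluorescence_slope(f, i)
  expect_equal(s2$slope, beta)
  expect_equal(s2$intercept, alpha)
  expect_error(fluorescence_slope(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fluorescence_slope(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("doubling the surface fraction doubles the cohort slope factor", {
  pr <- fast_protocol(sample_khz = 10)
  pas <- cell_passive_spec()
  wt <- clc4_variants()$WT
  chim <- clc4_variants("chimera")$WT_chimera  # surface fraction 2x WT
  co_wt <- simulate_cohort(wt, 12, pr, pas, seed = 21)
  co_ch <- simulate_cohort(chim, 12, pr, pas, seed = 22)
  get_slope <- function(co) {
    m <- analyze_cohort(co)$metrics
    fluorescence_slope(m$fluorescence, m$i_ss_max)$slope
  }
  ratio <- get_slope(co_ch) / get_slope(co_wt)
  expect_equal(ratio, 2, tolerance = 0.15)
})
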