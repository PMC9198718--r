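test_that("a single noise-free band integrates to its designed area", {
  spec <- gel_lane_spec(data.frame(label = "b", mw_kda = 110, area = 42,
                                   width = 1.4), baseline = 3, noise_sd = 0)
  lane <- synth_gel_lane(spec, 1)
  q <- quantify_roi(lane, 80, 140)
  expect_equal(q$total, 42, tolerance = 0.001)
  # band fully outside the ROI contributes nothing
  q2 <- quantify_roi(lane, 150, 250)
  expect_equal(q2$total, 0, tolerance = 0.05)
  expect_null(q2$per_band)
  expect_error(quantify_roi(lane, 140, 80), "mw_lo")
  expect_error(quantify_roi(lane, 10, 20000), "outside the calibrated")
})

test_that("migration position is strictly decreasing in molecular weight", {
  spec <- gel_lane_spec(data.frame(label = c("a", "b", "c"),
                                   mw_kda = c(250, 120, 60),
                                   area = c(1, 1, 1), width = rep(1, 3)))
  lane <- synth_gel_lane(spec, 1)
  expect_true(all(diff(lane$bands$position) > 0))  # smaller MW runs farther
  expect_equal(clc4quant:::position_to_mw(lane$bands$position, lane$mw_map),
               spec$bands$mw_kda, tolerance = 1e-9)
  expect_error(gel_lane_spec(data.frame(label = c("x", "x"),
                                        mw_kda = c(100, 120),
                                        area = c(1, 1), width = c(1, 1))),
               "duplicated")
})

test_that("overlapping bands are decomposed within 5% of truth", {
  spec <- gel_lane_spec(data.frame(label = c("b1", "b2"),
                                   mw_kda = c(118, 105),
                                   area = c(40, 60), width = c(1.6, 1.6)))
  for (s in 1:4) {
    lane <- synth_gel_lane(spec, s)
    q <- quantify_roi(lane, 80, 140)
    expect_equal(unname(q$per_band["b1"]), 40, tolerance = 0.05)
    expect_equal(unname(q$per_band["b2"]), 60, tolerance = 0.05)
  }
})

test_that("glycosylation fraction follows its defining arithmetic", {
  expect_equal(glycosylation_fraction(25, 75)$fraction, 0.25)
  expect_equal(glycosylation_fraction(0, 10)$fraction, 0)
  expect_error(glycosylation_fraction(0, 0), "undefined")
  # forced by a 1:3 area ratio through the full pipeline
  spec <- gel_lane_spec(data.frame(label = c("glycosylated", "core"),
                                   mw_kda = c(120, 100),
                                   area = c(1, 3), width = c(1.5, 1.2)),
                        noise_sd = 0.02)
  lane <- synth_gel_lane(spec, 2)
  q <- quantify_roi(lane, 80, 140)
  gf <- glycosylation_fraction(q$per_band[["glycosylated"]],
                               q$per_band[["core"]])
  expect_lt(abs(gf$fraction - 0.25), 0.02)
})

test_that("heterodimer fraction sums labeled species correctly", {
  only_het <- c(heterodimer_a = 3, heterodimer_b = 1)
  expect_equal(heterodimer_fraction(only_het)$fraction, 1)
  six <- stats::setNames(rep(10, 6),
                         c("m1", "m2", "d1", "d2", "heterodimer_1",
                           "heterodimer_2"))
  expect_equal(heterodimer_fraction(six)$fraction, 1 / 3)
  expect_error(heterodimer_fraction(c(m1 = 1, d1 = 2)), "missing")
  expect_error(heterodimer_fraction(unname(c(1, 2))), "labeled")
})

test_that("fractions are invariant under uniform lane rescaling", {
  spec <- gel_lane_spec(data.frame(label = c("glycosylated", "core"),
                                   mw_kda = c(120, 100),
                                   area = c(30, 60), width = c(1.5, 1.2)),
                        noise_sd = 0)
  lane <- synth_gel_lane(spec, 1)
  frac_of <- function(l) {
    q <- quantify_roi(l, 80, 140)
    glycosylation_fraction(q$per_band[["glycosylated"]],
                           q$per_band[["core"]])$fraction
  }
  lane2 <- lane
  lane2$intensity <- lane$intensity * 13.7
  expect_equal(frac_of(lane2), frac_of(lane), tolerance = 1e-6)
})

test_that("quantification is additive over disjoint ROIs", {
  spec <- gel_lane_spec(data.frame(label = c("a", "b"),
                                   mw_kda = c(200, 90),
                                   area = c(20, 50), width = c(1, 1)),
                        noise_sd = 0)
  lane <- synth_gel_lane(spec, 1)
  whole <- quantify_roi(lane, 60, 300, bands = NULL)$total
  lo <- quantify_roi(lane, 60, 130, bands = NULL)$total
  hi <- quantify_roi(lane, 130, 300, bands = NULL)$total
  expect_equal(lo + hi, whole, tolerance = 0.01)
})

test_that("designed proportions round-trip within 2% across a random sweep", {
  set.seed(9)
  for (rep in 1:6) {
    f <- runif(1, 0.15, 0.85)
    tot <- runif(1, 60, 140)
    spec <- gel_lane_spec(data.frame(
      label = c("glycosylated", "core"), mw_kda = c(120, 100),
      area = c(f * tot, (1 - f) * tot), width = runif(2, 1, 1.8)))
    lane <- synth_gel_lane(spec, sample.int(1e6, 1))
    q <- quantify_roi(lane, 80, 140)
    gf <- glycosylation_fraction(q$per_band[["glycosylated"]],
                                 q$per_band[["core"]])
    expect_lt(abs(gf$fraction - f), 0.02)
  }
})
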