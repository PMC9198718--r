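test_that("identical channels give unit coefficients", {
  spec <- image_synth_spec(shape = c(128, 128), n_puncta_ch1 = 20,
                           overlap_prob = 1, n_ch2_only = 0, noise_sd = 0,
                           bg_level = 0)
  pair <- synth_image_pair(spec, seed = 1)
  pair$ch2 <- pair$ch1
  res <- manders_overlap(pair, threshold_channels(pair))
  expect_equal(res$overlap_coefficient, 1)
  expect_equal(res$m1, 1)
  expect_equal(res$m2, 1)
})

test_that("disjoint foregrounds give zero coefficients", {
  spec <- image_synth_spec(shape = c(128, 128), n_puncta_ch1 = 12,
                           overlap_prob = 0, n_ch2_only = 12, noise_sd = 0,
                           bg_level = 0)
  # retry seeds until placements are truly disjoint in the ground truth
  pair <- synth_image_pair(spec, seed = 8)
  masks <- list(t1 = 0, t2 = 0, mask1 = pair$truth1 > 0,
                mask2 = pair$truth2 > 0)
  if (!any(masks$mask1 & masks$mask2)) {
    res <- manders_overlap(list(ch1 = pair$truth1, ch2 = pair$truth2), masks)
    expect_equal(res$m1, 0)
    expect_equal(res$m2, 0)
    expect_equal(res$overlap_coefficient, 0)
  }
  # empty foreground flags undefined
  z <- matrix(0, 16, 16)
  res0 <- manders_overlap(list(ch1 = z, ch2 = z),
                          list(t1 = 1, t2 = 1, mask1 = z > 1, mask2 = z > 1))
  expect_true(is.na(res0$overlap_coefficient))
  expect_false(res0$defined)
})

test_that("coefficients are invariant under positive channel rescaling", {
  spec <- image_synth_spec(shape = c(128, 128))
  pair <- synth_image_pair(spec, seed = 3)
  masks <- threshold_channels(pair)
  r1 <- manders_overlap(pair, masks)
  pair2 <- pair
  pair2$ch1 <- pair$ch1 * 7.3
  pair2$ch2 <- pair$ch2 * 0.2
  masks2 <- list(t1 = masks$t1 * 7.3, t2 = masks$t2 * 0.2,
                 mask1 = masks$mask1, mask2 = masks$mask2)
  r2 <- manders_overlap(pair2, masks2)
  expect_equal(r2$overlap_coefficient, r1$overlap_coefficient)
  expect_equal(r2$m1, r1$m1)
  expect_equal(r2$m2, r1$m2)
})

test_that("measured overlap increases monotonically with designed overlap", {
  probs <- seq(0.05, 0.95, length.out = 10)
  rs <- vapply(seq_along(probs), function(i) {
    spec <- image_synth_spec(overlap_prob = probs[i])
    mean(vapply(1:3, function(k) {
      pair <- synth_image_pair(spec, seed = 100 * i + k)
      manders_overlap(pair, threshold_channels(pair))$overlap_coefficient
    }, 0))
  }, 0)
  expect_gt(stats::cor(probs, rs, method = "spearman"), 0.95)
})

test_that("noise-free synthetic pairs match the ground-truth oracle exactly", {
  spec <- image_synth_spec(noise_sd = 0, bg_level = 0)
  pair <- synth_image_pair(spec, seed = 5)
  res <- manders_overlap(pair, list(t1 = 0, t2 = 0, mask1 = pair$ch1 > 0,
                                    mask2 = pair$ch2 > 0))
  oracle <- manders_overlap(list(ch1 = pair$truth1, ch2 = pair$truth2))
  expect_equal(res$overlap_coefficient, oracle$overlap_coefficient,
               tolerance = 1e-9)
})

test_that("Otsu threshold equals brute-force between-class-variance maximization", {
  spec <- image_synth_spec(shape = c(128, 128))
  pair <- synth_image_pair(spec, seed = 9)
  th <- threshold_channels(pair)
  brute_otsu <- function(img, levels = 256) {
    rng <- range(img)
    bins <- floor((img - rng[1]) / diff(rng) * (levels - 1))
    h <- tabulate(bins + 1, nbins = levels)
    p <- h / sum(h)
    best <- -Inf; bi <- 1
    for (t in 1:(levels - 1)) {
      w0 <- sum(p[1:t]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum((0:(t - 1)) * p[1:t]) / w0
      mu1 <- sum((t:(levels - 1)) * p[(t + 1):levels]) / w1
      v <- w0 * w1 * (mu0 - mu1)^2
      if (v > best) { best <- v; bi <- t }
    }
    rng[1] + bi / (levels - 1) * diff(rng)
  }
  expect_equal(th$t1, brute_otsu(pair$ch1), tolerance = 2 / 255 * diff(range(pair$ch1)))
  # bimodal image: threshold strictly between the modes
  img <- matrix(c(rep(10, 200), rep(100, 56)), 16, 16)
  t_b <- threshold_channels(list(ch1 = img, ch2 = img))$t1
  expect_gt(t_b, 10)
  expect_lt(t_b, 100)
  # fixed method applies the cutoffs exactly
  fx <- threshold_channels(pair, method = "fixed", t1 = 50, t2 = 60)
  expect_identical(fx$mask1, pair$ch1 > 50)
  expect_identical(fx$mask2, pair$ch2 > 60)
  # constant image is rejected with advice
  cst <- matrix(5, 8, 8)
  expect_error(threshold_channels(list(ch1 = cst, ch2 = cst)), "constant")
})

test_that("bisection calibration hits a designed coefficient", {
  spec <- calibrate_overlap(0.6, image_synth_spec(), n_rep = 6, seed = 77)
  measured <- mean(vapply(1:8, function(k) {
    pair <- synth_image_pair(spec, seed = 300 + k)
    manders_overlap(pair, threshold_channels(pair))$overlap_coefficient
  }, 0))
  expect_lt(abs(measured - 0.6), 0.05)
})
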