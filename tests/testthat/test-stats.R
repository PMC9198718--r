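test_that("ANOVA branch matches the textbook F statistic", {
  # two groups of three hand-computable values
  x <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("WT", "M"), each = 3)
  res <- compare_groups(x, g, reference = "WT")
  k <- 2; n <- 6
  gm <- mean(x)
  ssb <- 3 * ((mean(x[1:3]) - gm)^2 + (mean(x[4:6]) - gm)^2)
  ssw <- sum((x[1:3] - mean(x[1:3]))^2) + sum((x[4:6] - mean(x[4:6]))^2)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_identical(res$method, "anova_tukey")
  expect_equal(res$omnibus$statistic, f_oracle, tolerance = 1e-10)
})

test_that("an overwhelming shift earns three stars against the reference", {
  set.seed(4)
  vals <- c(rnorm(10, 0, 1), rnorm(10, 0, 1), rnorm(10, 5, 1))
  grp <- rep(c("WT", "A", "B"), each = 10)
  res <- compare_groups(vals, grp)
  pw <- res$pairwise
  expect_equal(pw$stars[pw$group == "B"], "***")
  expect_equal(pw$stars[pw$group == "A"], "ns")
})

test_that("assumption failures route to Mann-Whitney", {
  set.seed(8)
  vals <- c(rexp(12)^3, rexp(12)^3 + 4)  # heavily non-normal
  grp <- rep(c("WT", "M"), each = 12)
  res <- compare_groups(vals, grp)
  expect_identical(res$method, "mann_whitney")
  expect_true(any(res$gate$shapiro_p <= 0.05) || res$gate$levene_p <= 0.05)
  expect_null(res$omnibus)
  expect_true(all(res$pairwise$p >= 0 & res$pairwise$p <= 1))
})

test_that("undefined values are excluded but counted, small groups dropped", {
  set.seed(3)
  vals <- c(rnorm(8), NA, rnorm(7), 1, 2)
  grp <- c(rep("WT", 9), rep("A", 7), "B", "B")
  expect_warning(res <- compare_groups(vals, grp), "n < 3")
  expect_equal(res$n_excluded, 1)
  expect_setequal(res$pairwise$group, "A")
  expect_error(suppressWarnings(compare_groups(rnorm(4), rep("A", 4))),
               "at least 2 groups")
})

test_that("the decision gate is reproducible across reruns", {
  set.seed(12)
  vals <- rnorm(30)
  grp <- rep(c("WT", "A", "B"), each = 10)
  r1 <- compare_groups(vals, grp)
  r2 <- compare_groups(vals, grp)
  expect_identical(r1$method, r2$method)
  expect_identical(r1$pairwise, r2$pairwise)
})

test_that("star labels follow the printed thresholds", {
  expect_identical(star_label(c(0.2, 0.04, 0.009, 0.0009)),
                   c("ns", "*", "**", "***"))
})
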