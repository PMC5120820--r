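test_that("Bland-Altman matches hand-worked fixtures", {
  ba0 <- bland_altman(c(3, 4, 5), c(3, 4, 5))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)
  ba <- bland_altman(c(10, 12, 14), c(9, 12, 15))
  expect_equal(ba$differences, c(1, 0, -1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_half_width, 1.96)
  expect_equal(unname(ba$loa), c(-1.96, 1.96))
  expect_error(bland_altman(1, 2), class = "p4d_invalid_argument")
})

test_that("adding a constant shifts the bias, not the limits of agreement", {
  set.seed(2)
  a <- rnorm(20, 10); b <- rnorm(20, 10)
  ba <- bland_altman(a, b)
  ba2 <- bland_altman(a + 3.5, b)
  expect_equal(ba2$bias, ba$bias + 3.5)
  expect_equal(ba2$loa_half_width, ba$loa_half_width)
  # subject order does not matter
  o <- sample(20)
  ba3 <- bland_altman(a[o], b[o])
  expect_equal(ba3$bias, ba$bias)
  expect_equal(ba3$loa_half_width, ba$loa_half_width)
})

test_that("Bland-Altman recovers a known difference distribution", {
  set.seed(31)
  n <- 1e4; mu <- 0.7; sigma <- 1.3
  b <- rnorm(n, 50, 5)
  a <- b + rnorm(n, mu, sigma)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mu, tolerance = 0.05)
  expect_equal(ba$loa_half_width, 1.96 * sigma, tolerance = 0.05)
})

test_that("ICC is 1 for identical raters and matches the ANOVA oracle", {
  x <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  res <- icc_two_way(x)
  expect_equal(res$icc, 1)
  expect_true(res$good_agreement)
  set.seed(8)
  for (i in 1:5) {
    y <- matrix(rnorm(4 * 2, 10, 2), 4, 2) + rnorm(4)
    r2 <- icc_two_way(y, "ICC2_1")
    expect_equal(r2$icc, unname(bf_icc21(y)), tolerance = 1e-10)
    ms <- bf_anova_ms(y)
    expect_equal(unname(r2$ms), unname(ms), tolerance = 1e-10)
    expect_identical(r2$good_agreement, r2$icc > 0.75)
  }
})

test_that("consistency ICC is at least the agreement ICC under rater bias", {
  set.seed(9)
  subj <- rnorm(8, 20, 4)
  y <- cbind(subj + rnorm(8, 0, 1), subj + 2.5 + rnorm(8, 0, 1))
  icc2 <- icc_two_way(y, "ICC2_1")$icc
  icc3 <- icc_two_way(y, "ICC3_1")$icc
  expect_gte(icc3, icc2)
})

test_that("degenerate ICC input errors", {
  expect_error(icc_two_way(matrix(5, 3, 2)), class = "p4d_undefined_icc")
  expect_error(icc_two_way(matrix(1:3, 3, 1)), class = "p4d_invalid_argument")
})

test_that("Spearman correlation equals the mid-rank Pearson oracle", {
  expect_equal(spearman_corr(1:8, (1:8)^3), 1)
  expect_equal(spearman_corr(1:8, -(1:8)), -1)
  a <- c(1, 2, 2, 3); b <- c(1, 3, 2, 4)
  expect_equal(spearman_corr(a, b), bf_spearman(a, b))
  set.seed(13)
  for (i in 1:10) {
    x <- sample(1:5, 12, replace = TRUE); y <- sample(1:5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_corr(x, y), bf_spearman(x, y))
  }
  expect_error(spearman_corr(rep(1, 5), 1:5),
               class = "p4d_undefined_correlation")
  expect_error(spearman_corr(1:2, 2:3), class = "p4d_invalid_argument")
})

test_that("Welch t-test separates segmentation-time-like samples", {
  res <- two_sided_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$p, 1)
  set.seed(14)
  fast <- rnorm(14, 3.9, 1.8)     # computer-aided times, minutes
  slow <- rnorm(14, 20.8, 7.8)    # manual times
  res2 <- two_sided_ttest(fast, slow)
  expect_lt(res2$p, 0.001)
  res3 <- two_sided_ttest(slow, fast)
  expect_equal(res3$p, res2$p)
  expect_equal(res3$t, -res2$t)
  expect_error(two_sided_ttest(1, c(1, 2)), class = "p4d_invalid_argument")
})
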