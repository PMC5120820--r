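test_that("Hausdorff distance matches the hand cases", {
  expect_equal(hausdorff_distance(c(0.2, 0.8, 0.5), c(0.2, 0.8, 0.5)), 0)
  # two-point curves crossing: all pairwise distances are 1
  expect_equal(hausdorff_distance(c(0, 1), c(1, 0)), 1)
  expect_error(hausdorff_distance(1:3 / 3, 1:4 / 4),
               class = "p4d_invalid_argument")
})

test_that("distances equal a brute-force double-loop oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    a <- runif(n); b <- runif(n)
    expect_equal(hausdorff_distance(a, b), bf_hausdorff(a, b))
    expect_equal(hausdorff_distance(a, b, value_only = TRUE),
                 bf_hausdorff(a, b, value_only = TRUE))
  }
})

test_that("Hausdorff distance is a bounded pseudometric on sampled curves", {
  set.seed(5)
  for (i in 1:50) {
    n <- 10
    a <- runif(n); b <- runif(n); c3 <- runif(n)
    dab <- hausdorff_distance(a, b)
    expect_gte(dab, 0)
    expect_lte(dab, sqrt(2))
    expect_equal(dab, hausdorff_distance(b, a))
    expect_lte(dab, hausdorff_distance(a, c3) + hausdorff_distance(c3, b) + 1e-12)
  }
})

test_that("random null reproduces the requested moments", {
  null <- generate_random_null(n_curves = 10000, n_phases = 10, seed = 7)
  x <- as.vector(null$curves)
  expect_equal(mean(x), 0.5, tolerance = 0.01 / 0.5)
  expect_gte(sd(x), 0.186)
  expect_lte(sd(x), 0.200)   # clipping to [0,1] shrinks the SD slightly
  expect_true(all(x >= 0 & x <= 1))
})

test_that("the null is seeded and works with a single curve", {
  pw <- generate_pulse_template(10)
  n1 <- generate_random_null(14, seed = 3, pulse = pw)
  n2 <- generate_random_null(14, seed = 3, pulse = pw)
  expect_identical(n1$curves, n2$curves)
  expect_identical(n1$distances, n2$distances)
  expect_false(identical(generate_random_null(14, seed = 4)$curves, n1$curves))
  n3 <- generate_random_null(1, seed = 5, pulse = pw)
  expect_length(n3$distances, 1L)
})

test_that("pulsation test handles identical and separated samples", {
  res <- pulsation_test(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  set.seed(21)
  a <- rnorm(14, 0, 1); b <- rnorm(14, 5, 1)   # 5-SD shift
  res2 <- pulsation_test(a, b)
  expect_lt(res2$p, 1e-6)
  expect_error(pulsation_test(0.5, c(0.1, 0.2)), class = "p4d_invalid_argument")
})

test_that("curve classification separates flat, pulsatile and random", {
  pw <- generate_pulse_template(10)
  null <- generate_random_null(1000, seed = 17, pulse = pw, renorm = TRUE)
  expect_identical(classify_curve(rep(7, 10), pw, null), "flat")
  expect_identical(classify_curve(100 * (1 + 0.01 * as.numeric(pw)), pw, null),
                   "flat")  # amplitude 1.01 < 1.02
  expect_identical(classify_curve(100 * (1 + 0.05 * as.numeric(pw)), pw, null),
                   "pulsatile")
  # seeded random curves with amplitude above threshold: almost always "random"
  cls <- vapply(1:40, function(s) {
    cv <- 100 * (1 + 0.1 * generate_random_null(1, seed = s)$curves[1, ])
    classify_curve(cv, pw, null)
  }, character(1))
  expect_gte(mean(cls == "random"), 0.95)
})
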