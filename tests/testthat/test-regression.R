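test_that("unscaled MAD matches hand-computed values", {
  expect_equal(mad_raw(c(1, 1, 1)), 0)
  expect_equal(mad_raw(c(10, 20, 30, 30, 40, 50)), 10)
  expect_equal(mad_raw(1:5), 1)
  expect_error(mad_raw(numeric(0)), "finite")
})

test_that("origin OLS slope follows the closed form", {
  expect_equal(fit_origin_ols(c(1, 2, 3), c(2, 4, 6)), 2)
  expect_equal(fit_origin_ols(c(1, 2), c(2, 3)), 8 / 5)
  expect_equal(fit_origin_ols(seq(10, 50, 10), seq(10, 50, 10)), 1)
  # subset restriction
  expect_equal(fit_origin_ols(c(1, 2, 100), c(2, 4, 1), subset = 1:2), 2)
  expect_error(fit_origin_ols(c(0, 0), c(1, 2)), "degenerate")
  expect_error(fit_origin_ols(1, 1), "at least two")
})

test_that("RANSAC recovers the consensus slope on the six-peptide example", {
  x <- c(10, 20, 30, 40, 50, 60)
  y <- c(10, 20, 30, 40, 50, 30)
  fit <- ransac_fit(x, y, flq_config(), seed = 11)
  expect_equal(fit$slope, 1.0)
  expect_equal(unname(which(fit$inlier_mask)), 1:5)
  expect_equal(fit$residual_threshold, mad_raw(y)^2)
})

test_that("clean data give slope, full inlier set and r-squared of one", {
  x <- c(1, 2, 3, 4, 5)
  fit <- ransac_fit(x, x, flq_config(), seed = 2)
  expect_equal(fit$slope, 1)
  expect_true(all(fit$inlier_mask))
  expect_equal(fit$r_squared, 1)
  fit3 <- ransac_fit(x, 3 * x, flq_config(), seed = 2)
  expect_equal(fit3$slope, 3)
  expect_true(all(fit3$inlier_mask))
})

test_that("zero MAD admits only exact-residual peptides as inliers", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 4, 6, 8, 10, 12)  # mad(y) > 0 here, so perturb to constant-fit case
  yc <- rep(4, 6)             # mad = 0; only peptides with residual 0 qualify
  # y = beta*x can hit 4 exactly for at most one x per beta; consensus needs 2
  expect_error(ransac_fit(x, yc, flq_config(), seed = 1), "two inliers")
  expect_silent(ransac_fit(x, y, flq_config(), seed = 1))
})

test_that("fits are deterministic given a seed and reject bad input", {
  set.seed(42)
  x <- 10^runif(9, 5, 7)
  y <- x * exp(rnorm(9, 0, 0.1))
  f1 <- ransac_fit(x, y, flq_config(), seed = 99)
  f2 <- ransac_fit(x, y, flq_config(), seed = 99)
  expect_identical(f1$slope, f2$slope)
  expect_identical(f1$inlier_mask, f2$inlier_mask)
  expect_error(ransac_fit(c(-1, x[-1]), y, flq_config(), seed = 1),
               "strictly positive")
})

test_that("best-of-K equals the exhaustive subset oracle on small instances", {
  cfg <- flq_config()
  agree <- 0L
  n_cases <- 100L
  for (i in seq_len(n_cases)) {
    set.seed(i)
    n <- sample(5:8, 1)
    x <- 10^runif(n, 5, 7)
    f <- rep(1, n)
    n_mod <- sample(0:2, 1)
    if (n_mod > 0) f[sample(n, n_mod)] <- runif(n_mod, 0.1, 0.9)
    y <- x * f * exp(rnorm(n, 0, 0.03))
    oracle <- exhaustive_ransac_slope(x, y)
    fit <- best_of_k_fits(x, y, cfg, seed = 1000 + i)
    if (abs(fit$slope - oracle) <= 1e-9 * max(1, abs(oracle))) agree <- agree + 1L
  }
  expect_gte(agree / n_cases, 0.99)
})

test_that("best-of-K picks the first initiation when all agree", {
  x <- c(10, 20, 30, 40, 50, 60)
  y <- c(10, 20, 30, 40, 50, 30)
  fit <- best_of_k_fits(x, y, flq_config(), seed = 5)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$initiation_index, 1L)
  clean <- best_of_k_fits(x, 2 * x, flq_config(), seed = 5)
  expect_equal(clean$initiation_index, 1L)
  expect_equal(clean$slope, 2)
})

test_that("configuration invariants are enforced", {
  expect_error(flq_config(cutoff_likely = 0.6, cutoff_possibly = 0.5),
               "cutoff_likely")
  expect_error(flq_config(min_peptides = 2))
  expect_error(flq_config(min_samples_fraction = 0))
})
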