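test_that("raw scores are measured over expected intensity", {
  x <- c(10, 20, 60)
  expect_equal(raw_scores(x, 2 * x, 2), c(1, 1, 1))
  expect_equal(raw_scores(60, 30, 1), 0.5)
  expect_equal(raw_scores(60, 0, 1), 0)   # complete loss of unmodified signal
  expect_error(raw_scores(x, x, 0), "positive slope")
  expect_error(raw_scores(c(0, 20, 60), c(1, 2, 3), 1), "strictly positive")
})

test_that("outlier gate flags only scores strictly above median + 3*MAD", {
  g <- flag_high_outliers(c(1, 1, 1, 1, 1, 0.5))
  expect_equal(g$threshold, 1)
  expect_false(any(g$flags))
  g2 <- flag_high_outliers(c(1.0, 1.0, 1.02, 0.98, 2.0))
  expect_equal(g2$threshold, 1.06)
  expect_equal(which(g2$flags), 5L)
  expect_false(any(flag_high_outliers(rep(0.7, 3))$flags))
})

test_that("RM scaling uses the median of the three highest surviving scores", {
  r <- rm_scores(c(1, 1, 1, 1, 1, 0.5))
  expect_equal(r$scaling_factor, 1)
  expect_equal(r$rm, c(1, 1, 1, 1, 1, 0.5))
  r2 <- rm_scores(c(0.9, 1.0, 1.1, 0.5))
  expect_equal(r2$scaling_factor, 1.0)
  expect_equal(r2$rm, c(0.9, 1.0, 1.1, 0.5))
  r3 <- rm_scores(rep(0.37, 5))
  expect_equal(r3$rm, rep(1, 5))
  # flagged peptides keep no RM and do not enter the top-3
  r4 <- rm_scores(c(2, 1, 1, 1, 0.4), flags = c(TRUE, rep(FALSE, 4)))
  expect_equal(r4$scaling_factor, 1)
  expect_true(is.na(r4$rm[1]))
  expect_error(rm_scores(c(1, 1, 1), flags = c(TRUE, FALSE, FALSE)),
               "fewer than three")
})

test_that("classification boundaries sit exactly at the cutoffs", {
  cfg <- flq_config()
  expect_equal(classify_rm(0.49, cfg), "likely")
  expect_equal(classify_rm(0.5, cfg), "possibly")
  expect_equal(classify_rm(0.6, cfg), "likely_not")
  expect_equal(classify_rm(c(NA, 0.2, 0.55, 0.99), cfg),
               c("removed_outlier", "likely", "possibly", "likely_not"))
})

test_that("the six-peptide protein is scored end to end as expected", {
  x <- c(10, 20, 30, 40, 50, 60)
  vals <- rbind(ref = x, s1 = c(10, 20, 30, 40, 50, 30))
  tab <- intensity_table(vals, rep("A", 6), paste0("p", 1:6),
                         c("ref", "s1"), "ref")
  res <- analyze_protein(tab, "A", flq_config(), seed = 3)
  expect_equal(unname(res$rm_scores["s1", ]), c(1, 1, 1, 1, 1, 0.5))
  expect_equal(unname(res$raw_scores["s1", ]), c(1, 1, 1, 1, 1, 0.5))
  expect_false(any(res$flags))
  expect_equal(res$diagnostics$slope[res$diagnostics$sample == "s1"], 1.0)
  expect_equal(res$calls$category, c(rep("likely_not", 5), "possibly"))
})

test_that("identity sample scores RM = 1 everywhere, calls likely_not", {
  tab <- make_clean_table(n_peptides = 10, seed = 4)
  res <- analyze_protein(tab, "A", flq_config(), seed = 8)
  expect_equal(unname(res$rm_scores), matrix(1, 3, 10), tolerance = 1e-12)
  expect_true(all(res$calls$category == "likely_not"))
})

test_that("a global abundance change is absorbed by the slope", {
  tab <- make_clean_table(n_peptides = 9, seed = 5,
                          spikes = list(list(sample = "s2",
                                             peptide = 1:9, factor = 2)))
  res <- analyze_protein(tab, "A", flq_config(), seed = 8)
  expect_equal(res$diagnostics$slope[res$diagnostics$sample == "s2"], 2,
               tolerance = 1e-9)
  expect_equal(unname(res$rm_scores["s2", ]), rep(1, 9), tolerance = 1e-9)
})

test_that("RM scores are invariant to rescaling sample or reference", {
  set.seed(6)
  x <- 10^runif(10, 5, 7)
  y <- x * exp(rnorm(10, 0, 0.05))
  y[4] <- y[4] * 0.4
  base <- function(xx, yy) {
    fit <- best_of_k_fits(xx, yy, flq_config(), seed = 21)
    rm_via(xx, yy, fit$slope)
  }
  r0 <- base(x, y)
  expect_equal(base(x, 7 * y), r0, tolerance = 1e-9)
  expect_equal(base(x / 3, y), r0, tolerance = 1e-9)
})

test_that("RM scores do not depend on the fitted slope value", {
  # raw scores share the 1/beta factor; the gate and top-3 scaling are
  # positively homogeneous, so any fixed beta > 0 gives identical RM
  set.seed(7)
  x <- 10^runif(12, 5, 7)
  y <- x * exp(rnorm(12, 0, 0.05))
  y[c(2, 9)] <- y[c(2, 9)] * c(0.3, 0.6)
  beta <- best_of_k_fits(x, y, flq_config(), seed = 31)$slope
  expect_lte(max(abs(rm_via(x, y, beta) - rm_via(x, y, 2 * beta))), 1e-9)
})

test_that("a clean spike factor is recovered exactly as its RM score", {
  for (f in c(0.05, 0.3, 0.62, 0.95)) {
    tab <- make_clean_table(n_peptides = 8, seed = 9,
                            spikes = list(list(sample = "s1",
                                               peptide = 4, factor = f)))
    res <- analyze_protein(tab, "A", flq_config(), seed = 13)
    expect_equal(unname(res$rm_scores["s1", 4]), f, tolerance = 1e-6)
  }
})

test_that("decreasing one peptide's intensity never raises its RM score", {
  set.seed(10)
  x <- 10^runif(10, 5, 7)
  y0 <- x
  prev <- Inf
  for (f in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    y <- y0; y[6] <- y0[6] * f
    fit <- best_of_k_fits(x, y, flq_config(), seed = 17)
    rmv <- rm_via(x, y, fit$slope)
    expect_lte(rmv[6], prev + 1e-12)
    prev <- rmv[6]
  }
})

test_that("modification extent and RM score sum to one", {
  tab <- make_clean_table(n_peptides = 7, seed = 11,
                          spikes = list(list(sample = "s1",
                                             peptide = 2, factor = 0.25)))
  res <- analyze_protein(tab, "A", flq_config(), seed = 19)
  ok <- !is.na(res$rm_scores)
  expect_identical(res$modification_extent[ok], 1 - res$rm_scores[ok])
  expect_equal(res$modification_extent[ok] + res$rm_scores[ok],
               rep(1, sum(ok)), tolerance = 1e-15)
})

test_that("peptides with zero reference intensity are excluded up front", {
  vals <- rbind(ref1 = c(10, 0, 30), ref2 = c(12, 0, 34), s1 = c(11, 5, 32))
  tab <- intensity_table(vals, rep("A", 3), paste0("p", 1:3),
                         c("ref1", "ref2", "s1"), c("ref1", "ref2"))
  expect_warning(ref <- median_reference_vector(tab, "A"), "zero or missing")
  expect_equal(unname(ref$x), c(11, 32))
  expect_equal(ref$excluded, "A::p2")
})

test_that("proteins below the peptide minimum are skipped with advice", {
  tab <- make_clean_table(n_peptides = 4, seed = 12)
  expect_warning(res <- analyze_protein(tab, "A", flq_config(), seed = 1),
                 "superprotein")
  expect_null(res)
})
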