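test_that("the generator honors its contract", {
  p <- synth_params(n_proteins = 20, seed = 5)
  tab <- generate_dataset(p)
  counts <- table(tab$proteins)
  expect_true(all(counts >= 5 & counts <= 17))
  expect_equal(length(tab$sample_ids), 3L)
  expect_equal(tab$reference, tab$sample_ids)
  expect_true(all(tab$values > 0))
  # determinism
  expect_identical(generate_dataset(p)$values, tab$values)
  # noiseless limit: replicates identical
  t0 <- generate_dataset(synth_params(n_proteins = 3, cv = 0, seed = 2))
  expect_equal(t0$values[1, ], t0$values[2, ])
  expect_equal(t0$values[1, ], t0$values[3, ])
})

test_that("in-silico modification multiplies all replicates by the factor", {
  tab <- generate_dataset(synth_params(n_proteins = 5, seed = 6))
  mods <- apply_insilico_modifications(tab, k = 4, seed = 7)
  expect_equal(nrow(mods$truth), 20L)
  expect_equal(mods$truth$expected_change, 1 - mods$truth$f)
  ratio <- mods$modified$values / tab$values
  for (i in seq_len(nrow(mods$truth))) {
    col <- mods$truth$peptide_key[i]
    expect_equal(unname(ratio[, col]), rep(mods$truth$f[i], 3),
                 tolerance = 1e-12)
  }
  untouched <- setdiff(colnames(tab$values), mods$truth$peptide_key)
  expect_equal(ratio[, untouched], matrix(1, 3, length(untouched),
               dimnames = list(tab$sample_ids, untouched)))
  # boundary factors are legal: f = 1 leaves intensities unchanged, f = 0 zeroes
  v <- tab$values[, 1, drop = FALSE]
  expect_equal(v * 1, v)
  expect_equal(unique(as.numeric(v * 0)), 0)
  expect_error(apply_insilico_modifications(tab, k = 100), "fewer than")
})

test_that("benchmark evaluation reproduces the identity case exactly", {
  truth <- data.frame(f = c(0.2, 0.55, 0.9, 0.3),
                      expected_change = 1 - c(0.2, 0.55, 0.9, 0.3),
                      n_peptides = c(5, 8, 12, 15))
  rep_id <- evaluate_benchmark(rep(1, 4), truth$f, truth, flq_config())
  expect_equal(rep_id$pearson_r, 1)
  expect_equal(rep_id$mean_error, 0)
  expect_equal(rep_id$frac_error_below_0.1, 1)
  cls <- rep_id$classes
  expect_equal(cls$sensitivity[cls$n_true > 0], rep(1, sum(cls$n_true > 0)))
  expect_equal(cls$precision[cls$n_true > 0], rep(1, sum(cls$n_true > 0)))
})

test_that("the error metric behaves under direct simulated noise", {
  # no scorer involved: observed = expected + N(0, 0.02)
  set.seed(8)
  n <- 1000
  f <- runif(n)
  truth <- data.frame(f = f, expected_change = 1 - f,
                      n_peptides = sample(5:17, n, replace = TRUE))
  observed_rm <- f + rnorm(n, 0, 0.02)
  rep_sim <- evaluate_benchmark(rep(1, n), observed_rm, truth, flq_config())
  expect_gte(rep_sim$frac_error_below_0.1, 0.99)
  expect_gte(rep_sim$pearson_r, 0.99)
})

test_that("a peptide with f = 0.3 scored at RM = 0.3 counts as a true positive", {
  truth <- data.frame(f = c(0.3, 0.8), expected_change = c(0.7, 0.2),
                      n_peptides = c(6, 6))
  rep1 <- evaluate_benchmark(c(1, 1), c(0.3, 0.8), truth, flq_config())
  likely <- rep1$classes[rep1$classes$class == "likely", ]
  expect_equal(likely$sensitivity, 1)
  expect_equal(likely$precision, 1)
  expect_equal(likely$n_true, 1L)
})

test_that("degenerate truth variance yields an undefined correlation", {
  truth <- data.frame(f = rep(0.5, 4), expected_change = rep(0.5, 4),
                      n_peptides = rep(6, 4))
  rep0 <- evaluate_benchmark(rep(1, 4), rep(0.5, 4), truth, flq_config())
  expect_true(is.na(rep0$pearson_r))
})

test_that("a small end-to-end benchmark recovers imposed factors", {
  bm <- run_benchmark(synth_params(n_proteins = 12, seed = 3), k = 4,
                      seed = 17)
  cc <- bm$report$cases
  big <- cc[cc$n_peptides >= 8, ]
  expect_gte(stats::cor(big$expected_change, big$observed_change), 0.98)
  expect_lte(mean(big$error), 0.05)
})

test_that("slope clustering separates distinct outcomes at tolerance", {
  cl <- flexiquantLF:::cluster_slopes(c(1, 1 + 1e-9, 2, 2 * (1 + 1e-8), 3))
  expect_equal(cl$sizes, c(2L, 2L, 1L))
  expect_equal(cl$centers[3], 3)
})

test_that("a clean protein shows no ambiguity at any initiation count", {
  tab <- make_clean_table(n_peptides = 8, samples = c("ref", "s1"), seed = 13)
  rep_an <- reproducibility_analysis(tab, "A", flq_config(), n_runs = 20,
                                     ladder = c(1L, 5L), seed = 3)
  expect_true(all(!rep_an$outcomes$ambiguous))
  expect_equal(rep_an$by_k$n_ambiguous_samples, c(0L, 0L))
})

test_that("extra initiations reduce ambiguity on a two-consensus instance", {
  inst <- two_consensus_xy()
  vals <- rbind(ref = inst$x, s1 = inst$y)
  tab <- intensity_table(vals, rep("A", 8), sprintf("p%d", 1:8),
                         c("ref", "s1"), "ref")
  cfg <- flq_config(max_trials = 4L)
  rep_an <- reproducibility_analysis(tab, "A", cfg, n_runs = 150,
                                     ladder = c(1L, 30L), seed = 11)
  o <- rep_an$outcomes
  expect_true(o$ambiguous[o$K == 1])
  # the modal (optimal) outcome becomes dominant with more initiations
  expect_gt(o$modal_frequency[o$K == 30], o$modal_frequency[o$K == 1])
})
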