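#' Parameters of the synthetic intensity generator
#'
#' Describes a complete (no missing values) label-free peptide intensity
#' experiment: per-peptide baseline intensities drawn log-normally and
#' replicates scattered around them with multiplicative noise. Defaults
#' emulate a filtered DIA peptide report: 5-17 peptides per protein, three
#' replicates, 5% coefficient of variation, baselines spanning the typical
#' LC-MS intensity range (log10 location 6, scale 0.8).
#'
#' @param n_proteins Number of proteins.
#' @param peptides_range Length-2 integer range of peptides per protein
#'   (drawn uniformly).
#' @param n_replicates Replicates per condition.
#' @param log10_location,log10_scale Mean and SD of the peptide baseline
#'   intensity on the log10 scale.
#' @param cv Multiplicative coefficient of variation of replicate noise;
#'   the log-normal sigma is `sqrt(log(1 + cv^2))`.
#' @param seed Integer seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_proteins = 100L, peptides_range = c(5L, 17L),
                         n_replicates = 3L, log10_location = 6,
                         log10_scale = 0.8, cv = 0.05, seed = NULL) {
  stopifnot(n_proteins >= 1, n_replicates >= 1, cv >= 0,
            length(peptides_range) == 2L,
            peptides_range[1] >= 1, peptides_range[2] >= peptides_range[1])
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_range = as.integer(peptides_range),
                 n_replicates = as.integer(n_replicates),
                 log10_location = log10_location,
                 log10_scale = log10_scale, cv = cv,
                 seed = seed),
            class = "synth_params")
}

#' Generate a synthetic complete peptide intensity table
#'
#' Every peptide gets a log-normal baseline intensity; every replicate
#' observes `baseline * exp(N(0, sigma))` with `sigma = sqrt(log(1+cv^2))`.
#' The replicates form the reference group of the returned table (the
#' unmodified condition); deterministic given `params$seed`.
#'
#' @param params A [synth_params()].
#' @return An [intensity_table()] with `n_replicates` rows.
#' @export
generate_dataset <- function(params = synth_params()) {
  if (!is.null(params$seed))
    set.seed(as.integer(as.numeric(params$seed) %% .Machine$integer.max))
  n_pep <- sample.int(params$peptides_range[2] - params$peptides_range[1] + 1L,
                      params$n_proteins, replace = TRUE) +
           params$peptides_range[1] - 1L
  proteins <- rep(sprintf("P%04d", seq_len(params$n_proteins)), n_pep)
  peptides <- unlist(lapply(n_pep, function(k) sprintf("pep%02d", seq_len(k))))
  total <- sum(n_pep)
  baseline <- 10^stats::rnorm(total, params$log10_location, params$log10_scale)
  sigma <- sqrt(log(1 + params$cv^2))
  noise <- matrix(stats::rnorm(params$n_replicates * total, 0, sigma),
                  nrow = params$n_replicates)
  vals <- sweep(exp(noise), 2L, baseline, `*`)
  ids <- sprintf("rep%d", seq_len(params$n_replicates))
  intensity_table(vals, proteins, peptides, ids, reference = ids)
}

#' Impose in-silico modifications with known reduction factors
#'
#' For each protein, `k` distinct peptides are chosen uniformly at random
#' and each chosen peptide's intensity is multiplied by its own reduction
#' factor `f ~ U(0, 1)` in every replicate, simulating the intensity loss
#' of the unmodified species when a fraction `1 - f` of the protein is
#' modified at that peptide. The input table is not altered.
#'
#' @param table An [intensity_table()] (the unmodified condition).
#' @param k Modified peptides per protein (every protein must have >= k).
#' @param seed Integer seed.
#' @return A list: `modified` (the perturbed `intensity_table`) and
#'   `truth`, a data frame with one row per modified peptide (`protein`,
#'   `peptide_key`, `f`, `expected_change` = 1 - f, `n_peptides` of the
#'   protein).
#' @export
apply_insilico_modifications <- function(table, k = 4L, seed = NULL) {
  if (!is.null(seed))
    set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  proteins <- unique(table$proteins)
  counts <- table(table$proteins)[proteins]
  if (any(counts < k))
    stop("protein(s) with fewer than k = ", k, " peptides: ",
         paste(names(counts)[counts < k], collapse = ", "))
  vals <- table$values
  truth <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    cols <- which(table$proteins == proteins[i])
    chosen <- sort(sample(cols, k))
    f <- stats::runif(k, 0, 1)
    vals[, chosen] <- sweep(vals[, chosen, drop = FALSE], 2L, f, `*`)
    truth[[i]] <- data.frame(protein = proteins[i],
                             peptide_key = colnames(vals)[chosen],
                             f = f, expected_change = 1 - f,
                             n_peptides = length(cols),
                             stringsAsFactors = FALSE)
  }
  modified <- intensity_table(vals, table$proteins, table$peptides,
                              table$sample_ids, table$reference, table$groups)
  list(modified = modified, truth = do.call(rbind, truth))
}

#' Run the in-silico modification benchmark
#'
#' Generates a synthetic table, imposes known per-peptide reduction
#' factors, and scores both the unmodified and the modified replicates
#' against the unmodified replicate medians (both runs share one combined
#' table, so the reference is identical). Each modified replicate is scored
#' individually; each (modified peptide, replicate) pair is one benchmark
#' case.
#'
#' @param params A [synth_params()].
#' @param k Modified peptides per protein.
#' @param config An [flq_config()].
#' @param seed Integer master seed (generation, modification and fitting
#'   seeds derive from it deterministically).
#' @return A list: `report` (a [evaluate_benchmark()] report), `cases`
#'   (per-case data frame), `truth`.
#' @export
run_benchmark <- function(params = synth_params(), k = 4L,
                          config = flq_config(), seed = 1L) {
  seed <- as.numeric(seed)
  params$seed <- seed
  base <- generate_dataset(params)
  mods <- apply_insilico_modifications(base, k, seed = seed + 1)

  nrep <- params$n_replicates
  unmod_ids <- sprintf("unmod_rep%d", seq_len(nrep))
  mod_ids <- sprintf("mod_rep%d", seq_len(nrep))
  combined <- intensity_table(
    rbind(base$values, mods$modified$values),
    base$proteins, base$peptides,
    sample_ids = c(unmod_ids, mod_ids),
    reference = unmod_ids)

  proteins <- unique(combined$proteins)
  cases <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    res <- analyze_protein(combined, proteins[i], config,
                           seed = seed + 2 + (i - 1) * 1000000)
    tr <- mods$truth[mods$truth$protein == proteins[i], , drop = FALSE]
    pep <- tr$peptide_key
    cases[[i]] <- do.call(rbind, lapply(seq_len(nrep), function(r) {
      data.frame(protein = proteins[i], peptide_key = pep, replicate = r,
                 f = tr$f, expected_change = tr$expected_change,
                 n_peptides = tr$n_peptides,
                 rm_unmodified = res$rm_scores[unmod_ids[r], pep],
                 rm_modified = res$rm_scores[mod_ids[r], pep],
                 stringsAsFactors = FALSE)
    }))
  }
  cases <- do.call(rbind, cases)
  rownames(cases) <- NULL
  report <- evaluate_benchmark(cases$rm_unmodified, cases$rm_modified,
                               cases, config)
  list(report = report, cases = report$cases, truth = mods$truth)
}

#' Evaluate benchmark recovery of imposed modifications
#'
#' The observed change of a modified peptide is the relative RM drop
#' `(rm_unmodified - rm_modified) / rm_unmodified`, compared against the
#' expected change `1 - f`. Reports the Pearson correlation, per-class
#' sensitivity and precision (true classes from the expected RM score `f`,
#' predicted classes from the computed modified-run RM score, both through
#' the same cutoffs), absolute-error statistics, and errors binned by
#' peptides per protein (5-7, 8-10, 11-13, 14-17).
#'
#' @param rm_unmodified,rm_modified RM scores per benchmark case from the
#'   unmodified and the modified run.
#' @param truth Data frame aligned with the score vectors, needing columns
#'   `f`, `expected_change` and `n_peptides`.
#' @param config An [flq_config()] supplying the class cutoffs.
#' @return A list of class `flq_benchmark_report`: `pearson_r`, `classes`
#'   (per-class sensitivity/precision data frame), `mean_error`,
#'   `sd_error`, `frac_error_below_0.1`, `error_by_peptide_bin`,
#'   `n_cases`, `n_unscored`, and the per-case table `cases`.
#' @export
evaluate_benchmark <- function(rm_unmodified, rm_modified, truth,
                               config = flq_config()) {
  stopifnot(length(rm_unmodified) == nrow(truth),
            length(rm_modified) == nrow(truth))
  cases <- truth
  cases$rm_unmodified <- rm_unmodified
  cases$rm_modified <- rm_modified
  scored <- is.finite(rm_unmodified) & is.finite(rm_modified) &
            rm_unmodified > 0
  n_unscored <- sum(!scored)
  cc <- cases[scored, , drop = FALSE]
  cc$observed_change <- (cc$rm_unmodified - cc$rm_modified) / cc$rm_unmodified
  cc$error <- abs(cc$expected_change - cc$observed_change)
  cc$true_class <- classify_rm(cc$f, config)
  cc$predicted_class <- classify_rm(cc$rm_modified, config)

  pearson_r <- if (stats::sd(cc$expected_change) == 0 ||
                   stats::sd(cc$observed_change) == 0) NA_real_
               else stats::cor(cc$expected_change, cc$observed_change)

  cls <- c("likely", "possibly", "likely_not")
  classes <- do.call(rbind, lapply(cls, function(cl) {
    tp <- sum(cc$true_class == cl & cc$predicted_class == cl)
    fn <- sum(cc$true_class == cl & cc$predicted_class != cl)
    fp <- sum(cc$true_class != cl & cc$predicted_class == cl)
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               n_true = tp + fn, n_predicted = tp + fp,
               stringsAsFactors = FALSE)
  }))

  bins <- cut(cc$n_peptides, breaks = c(4.5, 7.5, 10.5, 13.5, 17.5),
              labels = c("5-7", "8-10", "11-13", "14-17"))
  by_bin <- do.call(rbind, lapply(levels(bins), function(b) {
    e <- cc$error[!is.na(bins) & bins == b]
    data.frame(bin = b, n = length(e),
               mean_error = if (length(e)) mean(e) else NA_real_,
               sd_error = if (length(e) > 1) stats::sd(e) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  structure(list(pearson_r = pearson_r, classes = classes,
                 mean_error = mean(cc$error),
                 sd_error = stats::sd(cc$error),
                 frac_error_below_0.1 = mean(cc$error < 0.1),
                 error_by_peptide_bin = by_bin,
                 n_cases = nrow(cc), n_unscored = n_unscored,
                 cases = cc),
            class = "flq_benchmark_report")
}

#' @export
print.flq_benchmark_report <- function(x, ...) {
  cat("in-silico modification benchmark:", x$n_cases, "cases")
  if (x$n_unscored) cat(" (", x$n_unscored, " unscored)", sep = "")
  cat("\n  Pearson r (expected vs observed change):",
      formatC(x$pearson_r, digits = 4, format = "f"), "\n")
  cat("  mean |error|:", formatC(x$mean_error, digits = 4, format = "f"),
      " SD:", formatC(x$sd_error, digits = 4, format = "f"),
      " frac(error < 0.1):",
      formatC(x$frac_error_below_0.1, digits = 4, format = "f"), "\n")
  for (i in seq_len(nrow(x$classes)))
    cat(sprintf("  %-10s sensitivity %.3f  precision %.3f (n_true %d)\n",
                x$classes$class[i], x$classes$sensitivity[i],
                x$classes$precision[i], x$classes$n_true[i]))
  invisible(x)
}

#' RANSAC-initiation reproducibility analysis
#'
#' Measures how often repeated runs of the scorer land on different slopes,
#' and how extra initiations suppress that ambiguity. For each initiation
#' count K in `ladder` and each non-reference sample, [best_of_k_fits()] is
#' run `n_runs` times with distinct seeds; the resulting slopes are
#' clustered with relative tolerance `tol` and a sample is ambiguous when
#' more than one cluster appears.
#'
#' @param table An [intensity_table()].
#' @param protein Protein to analyze.
#' @param config An [flq_config()] (its `n_initiations` is overridden by
#'   the ladder).
#' @param n_runs Repeated runs per (K, sample).
#' @param ladder Initiation counts to test.
#' @param tol Relative tolerance defining distinct slope outcomes.
#' @param seed Integer seed.
#' @return A list: `by_k` (data frame: K, ambiguous-sample count) and
#'   `outcomes` (per K and sample: number of distinct slopes and the modal
#'   outcome frequency).
#' @export
reproducibility_analysis <- function(table, protein, config = flq_config(),
                                     n_runs = 1000L,
                                     ladder = c(1L, seq(10L, 100L, 10L)),
                                     tol = 1e-6, seed = 1L) {
  ref <- median_reference_vector(table, protein)
  samples <- setdiff(table$sample_ids, table$reference)
  if (!length(samples)) samples <- table$sample_ids
  seed <- as.numeric(seed)
  outcomes <- list()
  for (K in ladder) {
    cfg <- config
    cfg$n_initiations <- as.integer(K)
    for (s in samples) {
      y <- table$values[s, ref$columns]
      slopes <- vapply(seq_len(n_runs), function(r) {
        best_of_k_fits(ref$x, y, cfg,
                       seed = seed + r * 101 + K * 13)$slope
      }, numeric(1))
      cl <- cluster_slopes(slopes, tol)
      outcomes[[length(outcomes) + 1L]] <- data.frame(
        K = K, sample = s, n_outcomes = length(cl$sizes),
        modal_frequency = max(cl$sizes) / n_runs,
        ambiguous = length(cl$sizes) > 1L, stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, outcomes)
  by_k <- stats::aggregate(ambiguous ~ K, outcomes, sum)
  names(by_k)[2] <- "n_ambiguous_samples"
  list(by_k = by_k, outcomes = outcomes)
}

# Greedy single-linkage clustering of slope outcomes at relative tolerance.
cluster_slopes <- function(slopes, tol = 1e-6) {
  o <- order(slopes)
  s <- slopes[o]
  breaks <- which(diff(s) > tol * pmax(abs(s[-length(s)]), .Machine$double.eps))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(s))
  list(centers = vapply(seq_along(starts),
                        function(i) stats::median(s[starts[i]:ends[i]]),
                        numeric(1)),
       sizes = ends - starts + 1L)
}
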