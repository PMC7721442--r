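#' Raw scores: measured over expected intensity
#'
#' The vertical distance of each peptide to the regression line, normalized
#' by the expected intensity and subtracted from one:
#' `s_j = 1 - (beta*x_j - y_j) / (beta*x_j) = y_j / (beta*x_j)`.
#' An unmodified, stably quantified peptide scores ~1; loss of unmodified
#' signal through modification pushes the score below 1 (0 = complete loss).
#'
#' @param x Strictly positive reference intensities.
#' @param y Sample intensities.
#' @param slope Positive fitted slope.
#' @return Numeric vector of raw scores.
#' @export
raw_scores <- function(x, y, slope) {
  if (!is.finite(slope) || slope <= 0)
    stop("raw scores require a positive slope")
  if (any(x <= 0)) stop("reference intensities must be strictly positive")
  y / (slope * x)
}

#' Flag high-side raw-score outliers
#'
#' Peptides with a raw score strictly above `median(s) + 3 * mad_raw(s)` are
#' flagged and excluded from RM scaling. Only the high side is gated: low
#' raw scores are the modification signal, and removed peptides are routed
#' to the removed-peptides report.
#'
#' @param s Raw scores.
#' @return List with logical `flags` and the numeric `threshold`.
#' @export
flag_high_outliers <- function(s) {
  if (!length(s)) stop("no raw scores")
  threshold <- stats::median(s) + 3 * mad_raw(s)
  # relative guard keeps ulp-level jitter from tripping the strict gate
  # when MAD(s) = 0 (exactly tied scores on noiseless data)
  list(flags = s > threshold + 1e-12 * pmax(1, abs(threshold)),
       threshold = threshold)
}

#' RM scores: raw scores scaled by the top-3 median
#'
#' Surviving raw scores are divided by the median of the three highest
#' surviving raw scores, anchoring unmodified peptides at RM ~ 1. The RM
#' score equals one minus the modification extent relative to the reference.
#'
#' @param s Raw scores.
#' @param flags Logical outlier flags from [flag_high_outliers()].
#' @return List with `rm` (NA for flagged peptides) and `scaling_factor`.
#' @export
rm_scores <- function(s, flags = rep(FALSE, length(s))) {
  keep <- which(!flags)
  if (length(keep) < 3L)
    stop("fewer than three unflagged raw scores; RM scaling undefined")
  top3 <- sort(s[keep], decreasing = TRUE)[1:3]
  scaling_factor <- top3[2L]  # median of exactly three values
  if (!is.finite(scaling_factor) || scaling_factor <= 0)
    stop("non-positive scaling factor; cannot compute RM scores")
  rm <- rep(NA_real_, length(s))
  rm[keep] <- s[keep] / scaling_factor
  list(rm = rm, scaling_factor = scaling_factor)
}

#' Classify an RM score
#'
#' Three-class call: `rm < cutoff_likely` = "likely" differentially
#' modified; `cutoff_likely <= rm < cutoff_possibly` = "possibly";
#' `rm >= cutoff_possibly` = "likely_not". `NA` maps to "removed_outlier".
#'
#' @param rm RM score(s).
#' @param config An [flq_config()] supplying the cutoffs.
#' @return Character vector of categories.
#' @export
classify_rm <- function(rm, config = flq_config()) {
  out <- ifelse(is.na(rm), "removed_outlier",
         ifelse(rm < config$cutoff_likely, "likely",
         ifelse(rm < config$cutoff_possibly, "possibly", "likely_not")))
  as.character(out)
}

# Shared scoring tail: raw scores -> outlier gate -> RM, for one sample.
# Fewer than three unflagged scores leaves the sample not evaluated
# (raw scores and flags are still reported, RM is NA).
score_sample <- function(x, y, fit) {
  s <- raw_scores(x, y, fit$slope)
  gate <- flag_high_outliers(s)
  if (sum(!gate$flags) >= 3L) {
    rmres <- rm_scores(s, gate$flags)
    list(raw = s, flags = gate$flags, outlier_threshold = gate$threshold,
         rm = rmres$rm, scaling_factor = rmres$scaling_factor,
         evaluated = TRUE)
  } else {
    list(raw = s, flags = gate$flags, outlier_threshold = gate$threshold,
         rm = rep(NA_real_, length(s)), scaling_factor = NA_real_,
         evaluated = FALSE)
  }
}

#' Score all samples of one protein
#'
#' The per-protein pipeline: the reference group is collapsed to a median
#' intensity vector, then for every sample a robust origin regression is
#' fitted ([best_of_k_fits()]), raw scores computed, high outliers flagged,
#' and RM scores derived. A per-peptide summary call is taken at a chosen
#' call sample (default: the last sample in table order). Reference samples
#' themselves are scored too and trivially sit near RM = 1.
#'
#' @param table An [intensity_table()], complete for this protein.
#' @param protein Protein identifier.
#' @param config An [flq_config()].
#' @param call_sample Sample identifier at which summary calls are made.
#' @param seed Integer seed; overrides `config$seed` when given.
#' @return A list of class `flq_result` with matrices `raw_scores`,
#'   `rm_scores`, `flags` (samples x peptides), a `diagnostics` data frame
#'   (slope, r-squared, inlier count, thresholds, scaling factor per
#'   sample), a `calls` data frame, `modification_extent` (1 - RM), and
#'   bookkeeping (`protein`, `excluded_peptides`, `call_sample`).
#' @export
analyze_protein <- function(table, protein, config = flq_config(),
                            call_sample = NULL, seed = config$seed) {
  ref <- median_reference_vector(table, protein)
  n <- length(ref$x)
  if (n < config$min_peptides) {
    warning("protein '", protein, "' has ", n, " usable peptides (< ",
            config$min_peptides, "); skipped. Consider pooling it into a ",
            "superprotein group.")
    return(NULL)
  }
  samples <- table$sample_ids
  if (is.null(call_sample)) call_sample <- samples[length(samples)]
  if (!call_sample %in% samples)
    stop("call sample '", call_sample, "' not in table")
  if (is.null(seed)) seed <- sample.int(1000000L, 1L)
  seed <- as.numeric(seed)

  pep_keys <- colnames(table$values)[ref$columns]
  nsamp <- length(samples)
  raw <- rm <- matrix(NA_real_, nsamp, n, dimnames = list(samples, pep_keys))
  flags <- matrix(FALSE, nsamp, n, dimnames = list(samples, pep_keys))
  diag <- data.frame(protein = protein, sample = samples, slope = NA_real_,
                     r_squared = NA_real_, n_inliers = NA_integer_,
                     residual_threshold = NA_real_,
                     outlier_threshold = NA_real_, scaling_factor = NA_real_,
                     initiation_index = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nsamp)) {
    y <- table$values[i, ref$columns]
    fit <- best_of_k_fits(ref$x, y, config,
                          seed = seed + (i - 1L) * 10000L)
    sc <- score_sample(ref$x, y, fit)
    raw[i, ] <- sc$raw
    rm[i, ] <- sc$rm
    flags[i, ] <- sc$flags
    diag$slope[i] <- fit$slope
    diag$r_squared[i] <- fit$r_squared
    diag$n_inliers[i] <- sum(fit$inlier_mask)
    diag$residual_threshold[i] <- fit$residual_threshold
    diag$outlier_threshold[i] <- sc$outlier_threshold
    diag$scaling_factor[i] <- sc$scaling_factor
    diag$initiation_index[i] <- fit$initiation_index
  }
  rm_call <- rm[call_sample, ]
  category <- classify_rm(unname(rm_call), config)
  if (is.na(diag$scaling_factor[match(call_sample, samples)]))
    category[] <- "not_evaluated"
  calls <- data.frame(protein = protein, peptide = table$peptides[ref$columns],
                      peptide_key = pep_keys, rm_score = unname(rm_call),
                      category = category, stringsAsFactors = FALSE)
  structure(list(protein = protein, raw_scores = raw, rm_scores = rm,
                 modification_extent = 1 - rm, flags = flags,
                 diagnostics = diag, calls = calls,
                 excluded_peptides = ref$excluded,
                 call_sample = call_sample),
            class = "flq_result")
}

#' @export
print.flq_result <- function(x, ...) {
  cat("flq_result for protein", x$protein, "-", ncol(x$rm_scores),
      "peptides x", nrow(x$rm_scores), "samples\n")
  cat("calls at", x$call_sample, ":",
      paste(names(table(x$calls$category)), table(x$calls$category),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
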