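#' Construct an intensity table
#'
#' The central container of the package: a samples-by-peptides matrix of
#' label-free peptide intensities, each peptide annotated with its parent
#' protein, plus the designation of one or more samples as the reference
#' group. All downstream regression and scoring operate on this object.
#'
#' @param values Numeric matrix, one row per sample and one column per
#'   peptide. Intensities must be finite and non-negative; `NA` marks a
#'   missing quantification (removed later by [filter_complete()]).
#' @param proteins Character vector of parent protein identifiers, one per
#'   column of `values`.
#' @param peptides Character vector of peptide identifiers, one per column.
#'   The pair (protein, peptide) must be unique.
#' @param sample_ids Character vector of sample identifiers, one per row.
#' @param reference Character vector of sample identifiers forming the
#'   reference group (non-empty, subset of `sample_ids`).
#' @param groups Optional character vector of group labels per sample,
#'   carried through to the output files.
#'
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, proteins, peptides, sample_ids,
                            reference, groups = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(proteins) || ncol(values) != length(peptides))
    stop("'proteins' and 'peptides' must have one entry per column of 'values'")
  if (nrow(values) != length(sample_ids))
    stop("'sample_ids' must have one entry per row of 'values'")
  keys <- paste(proteins, peptides, sep = "::")
  if (anyDuplicated(keys))
    stop("duplicate (protein, peptide) columns: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers")
  if (length(reference) == 0L)
    stop("reference group must contain at least one sample")
  missing_ref <- setdiff(reference, sample_ids)
  if (length(missing_ref))
    stop("reference sample(s) not present in table: ",
         paste(missing_ref, collapse = ", "))
  bad <- which(is.finite(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative intensity at sample '", sample_ids[bad[1, 1]],
         "', peptide '", keys[bad[1, 2]], "'")
  if (any(is.infinite(values)))
    stop("non-finite intensities in table")
  if (!is.null(groups) && length(groups) != length(sample_ids))
    stop("'groups' must have one entry per sample")
  dimnames(values) <- list(sample_ids, keys)
  structure(
    list(values = values,
         proteins = as.character(proteins),
         peptides = as.character(peptides),
         sample_ids = as.character(sample_ids),
         reference = as.character(reference),
         groups = if (is.null(groups)) NULL else as.character(groups)),
    class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", length(x$sample_ids), "samples x",
      ncol(x$values), "peptides,", length(unique(x$proteins)), "proteins\n")
  cat("reference group:", paste(x$reference, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

# Column indices of one protein's peptides.
protein_columns <- function(table, protein) {
  which(table$proteins == protein)
}

#' Restrict a table to completely quantified peptides
#'
#' Peptides with any missing or zero intensity in any sample are removed:
#' a zero cannot anchor the regression denominator and a missing value breaks
#' the per-sample fit. Removal counts per protein are reported via message.
#'
#' @param table An [intensity_table()].
#' @param quiet Suppress the attrition message.
#' @return The filtered `intensity_table`.
#' @export
filter_complete <- function(table, quiet = FALSE) {
  ok <- apply(table$values, 2L, function(v) all(is.finite(v) & v > 0))
  if (!all(ok) && !quiet) {
    dropped <- table(table$proteins[!ok])
    message("filter_complete: removed ", sum(!ok), " peptide(s) [",
            paste(names(dropped), dropped, sep = ": ", collapse = "; "), "]")
  }
  subset_peptides(table, ok)
}

subset_peptides <- function(table, keep) {
  intensity_table(table$values[, keep, drop = FALSE],
                  table$proteins[keep], table$peptides[keep],
                  table$sample_ids, table$reference, table$groups)
}

#' Collapse replicate samples to condition medians
#'
#' Each condition's intensity is the element-wise median across its
#' replicates, the conventional pre-processing step before scoring a
#' time-course (one condition per time point). Condition order follows the
#' order of first appearance in `replicate_map`.
#'
#' @param table An [intensity_table()].
#' @param replicate_map Data frame with columns `sample` and `condition`
#'   mapping every sample of `table` to exactly one condition.
#' @return An `intensity_table` with one row per condition. The reference
#'   group is translated to the conditions containing reference samples.
#' @export
aggregate_replicates <- function(table, replicate_map) {
  if (!all(c("sample", "condition") %in% names(replicate_map)))
    stop("'replicate_map' needs columns 'sample' and 'condition'")
  m <- match(table$sample_ids, replicate_map$sample)
  if (anyNA(m))
    stop("samples missing from replicate map: ",
         paste(table$sample_ids[is.na(m)], collapse = ", "))
  cond <- as.character(replicate_map$condition)[m]
  levels <- unique(as.character(replicate_map$condition))
  levels <- levels[levels %in% cond]
  if (!length(levels)) stop("replicate map yields no non-empty condition")
  agg <- t(vapply(levels, function(cd) {
    apply(table$values[cond == cd, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(table$values))))
  ref_cond <- unique(cond[table$sample_ids %in% table$reference])
  intensity_table(agg, table$proteins, table$peptides,
                  sample_ids = levels, reference = ref_cond)
}

#' Reference intensity vector for one protein
#'
#' Collapses the reference group to a single expected-intensity vector by
#' taking the element-wise median across reference samples. Peptides whose
#' reference intensity is zero or missing are unusable (the raw-score
#' denominator would be undefined) and are reported back as excluded.
#'
#' @param table An [intensity_table()].
#' @param protein Protein identifier present in `table`.
#' @return A list with `x` (named vector of positive reference intensities),
#'   `columns` (their column indices in the table) and `excluded`
#'   (peptide keys dropped for zero/missing reference intensity).
#' @export
median_reference_vector <- function(table, protein) {
  cols <- protein_columns(table, protein)
  if (!length(cols)) stop("protein '", protein, "' not found in table")
  ref_rows <- table$sample_ids %in% table$reference
  ref <- table$values[ref_rows, cols, drop = FALSE]
  x <- apply(ref, 2L, stats::median)
  usable <- is.finite(x) & x > 0
  if (!all(usable))
    warning("protein '", protein, "': excluding ", sum(!usable),
            " peptide(s) with zero or missing reference intensity")
  list(x = x[usable], columns = cols[usable],
       excluded = colnames(table$values)[cols[!usable]])
}
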