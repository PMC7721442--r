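#!/usr/bin/env Rscript
# Optional full-data reproduction on the deposited APC/C co-IP peptide
# intensities (ProteomeXchange PXD018411, "Supplementary file 1"). The data
# must be downloaded separately and reshaped to this package's wide layout
# (two header rows: protein, peptide; sample rows with ID and group); an
# optional annotations CSV (protein, peptide, modifications) enables the
# modification filter. A replicate-map CSV collapses replicates to time
# points before scoring, with time point 0 hr (S phase) as reference.
#
# Usage:
#   Rscript scripts/full_reproduction.R --input <wide.csv> --reference <label>
#       [--annotations <csv>] [--replicate-map <csv>]
#       [--superprotein <csv>] [--call-sample <id>] [--out-dir <dir>]
#
# Reports: peptide attrition under the filters, per-protein likely /
# possibly counts (CDC27 expected: 9 likely), RM scores of called peptides
# at the call sample, and the mean RM difference between superprotein and
# individual analyses.

suppressPackageStartupMessages(library(flexiquantLF))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
input <- get_arg("--input"); reference <- get_arg("--reference")
if (is.null(input) || is.null(reference))
  stop("--input and --reference are required")
ann_path <- get_arg("--annotations")
map_path <- get_arg("--replicate-map")
sp_path <- get_arg("--superprotein")
call_sample <- get_arg("--call-sample")
out_dir <- get_arg("--out-dir", "full_reproduction_out")

tab <- read_intensity_table(input, reference = reference)
n0 <- ncol(tab$values)
cat("peptides in input:", n0, "\n")

if (!is.null(ann_path)) {
  ann <- read.csv(ann_path, stringsAsFactors = FALSE)
  keep <- filter_allowed_modifications(ann)
  tab <- flexiquantLF:::subset_peptides(tab, colnames(tab$values) %in% keep)
  cat("after modification filter:", ncol(tab$values), "\n")
}
tab <- filter_complete(tab)
cat("after completeness filter:", ncol(tab$values), "\n")
if (!is.null(map_path)) {
  tab <- aggregate_replicates(tab, read.csv(map_path))
  cat("conditions after replicate aggregation:",
      paste(tab$sample_ids, collapse = ", "), "\n")
}

cfg <- flq_config(seed = 1L)
proteins <- unique(tab$proteins)
results <- list()
for (p in proteins) {
  r <- tryCatch(analyze_protein(tab, p, cfg, call_sample),
                warning = function(w) { message(conditionMessage(w)); NULL })
  if (!is.null(r)) results[[p]] <- r
}

cat("\nper-protein calls at",
    results[[1]]$call_sample, ":\n")
for (p in names(results)) {
  tabl <- table(results[[p]]$calls$category)
  cat(sprintf("  %-8s likely=%d possibly=%d removed=%d of %d peptides\n", p,
              sum(results[[p]]$calls$category == "likely"),
              sum(results[[p]]$calls$category == "possibly"),
              sum(results[[p]]$flags[results[[p]]$call_sample, ]),
              nrow(results[[p]]$calls)))
}

called <- do.call(rbind, lapply(results, function(r)
  r$calls[r$calls$category %in% c("likely", "possibly"), ]))
cat("\nRM scores of called peptides:\n")
print(called[order(called$protein, called$rm_score),
             c("protein", "peptide", "rm_score", "category")],
      row.names = FALSE)

if (!is.null(sp_path)) {
  groups <- read_superprotein_groups(sp_path)
  for (g in names(groups)) {
    sup <- analyze_superprotein(tab, groups[[g]]$members, cfg, call_sample)
    diffs <- unlist(lapply(groups[[g]]$members, function(p) {
      if (is.null(results[[p]])) return(NULL)
      abs(sup$per_protein[[p]]$rm_scores - results[[p]]$rm_scores)
    }))
    cat(sprintf("\nsuperprotein '%s': mean |RM difference| vs individual = %g\n",
                g, mean(diffs, na.rm = TRUE)))
    results[[paste0("superprotein_", g)]] <- sup
  }
}

write_results(results, tab, out_dir, base = "full_reproduction")
cat("\noutputs written to", out_dir, "\n")
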