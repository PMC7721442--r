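#' Read a peptide intensity table from CSV/TSV
#'
#' Two layouts are accepted. **Wide**: row 1 holds protein identifiers and
#' row 2 peptide identifiers (from the third column on), or a single header
#' row of `protein::peptide` keys; every following row is one sample with
#' sample ID in column 1 and group label in column 2. **Long**: a header of
#' `sample`, `protein`, `peptide`, `intensity` (plus optional `group`)
#' columns, pivoted to wide on read. Empty cells are missing values; any
#' other non-numeric intensity is an error naming the offending cell.
#'
#' @param path Path to the file. `.tsv`/`.txt` extensions are read as
#'   tab-separated, everything else as comma-separated.
#' @param layout `"auto"` (default), `"wide"` or `"long"`.
#' @param reference Either a group label (samples whose group column equals
#'   it form the reference) or a character vector of sample IDs.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path, layout = c("auto", "wide", "long"),
                                 reference) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"",
                           blank.lines.skip = TRUE)
  if (layout == "auto") {
    hdr <- tolower(trimws(unlist(raw[1, ])))
    layout <- if (all(c("sample", "protein", "peptide", "intensity") %in% hdr))
      "long" else "wide"
  }
  if (layout == "long") parse_long(raw, reference, path)
  else parse_wide(raw, reference, path)
}

parse_cell <- function(chr, row, col, path) {
  chr <- trimws(chr)
  out <- rep(NA_real_, length(chr))
  filled <- !is.na(chr) & nzchar(chr)
  suppressWarnings(out[filled] <- as.numeric(chr[filled]))
  bad <- filled & is.na(out)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-numeric intensity '", chr[i], "' in ", basename(path),
         " at row ", row[i], ", column ", col[i])
  }
  out
}

parse_wide <- function(raw, reference, path) {
  if (ncol(raw) < 3L) stop("wide layout needs at least three columns")
  first_data <- trimws(unlist(raw[1, -(1:2)]))
  double_header <- !all(grepl("::", first_data, fixed = TRUE))
  if (double_header) {
    if (nrow(raw) < 3L) stop("wide layout with two header rows needs sample rows")
    proteins <- trimws(unlist(raw[1, -(1:2)]))
    peptides <- trimws(unlist(raw[2, -(1:2)]))
    body <- raw[-(1:2), , drop = FALSE]
    skip <- 2L
  } else {
    proteins <- sub("::.*$", "", first_data)
    peptides <- sub("^.*?::", "", first_data)
    body <- raw[-1, , drop = FALSE]
    skip <- 1L
  }
  sample_ids <- trimws(body[[1]])
  groups <- trimws(body[[2]])
  npep <- length(proteins)
  vals <- matrix(NA_real_, nrow(body), npep)
  for (j in seq_len(npep)) {
    vals[, j] <- parse_cell(body[[j + 2L]], row = skip + seq_len(nrow(body)),
                            col = rep(j + 2L, nrow(body)), path = path)
  }
  ref <- resolve_reference(reference, sample_ids, groups)
  intensity_table(vals, proteins, peptides, sample_ids, ref, groups)
}

parse_long <- function(raw, reference, path) {
  hdr <- tolower(trimws(unlist(raw[1, ])))
  names(raw) <- hdr
  df <- raw[-1, , drop = FALSE]
  int <- parse_cell(df$intensity, row = 1L + seq_len(nrow(df)),
                    col = rep(match("intensity", hdr), nrow(df)), path = path)
  key <- paste(trimws(df$protein), trimws(df$peptide), sep = "::")
  sample_ids <- unique(trimws(df$sample))
  keys <- unique(key)
  if (anyDuplicated(paste(df$sample, key)))
    stop("duplicate (sample, protein, peptide) records in long input")
  vals <- matrix(NA_real_, length(sample_ids), length(keys),
                 dimnames = list(sample_ids, keys))
  vals[cbind(match(trimws(df$sample), sample_ids), match(key, keys))] <- int
  groups <- NULL
  if ("group" %in% hdr) {
    g <- tapply(trimws(df$group), trimws(df$sample), function(v) v[1])
    groups <- unname(g[sample_ids])
  }
  ref <- resolve_reference(reference, sample_ids, groups)
  intensity_table(vals, sub("::.*$", "", keys), sub("^.*?::", "", keys),
                  sample_ids, ref, groups)
}

resolve_reference <- function(reference, sample_ids, groups) {
  if (missing(reference) || is.null(reference))
    stop("a reference group label or reference sample IDs must be given")
  if (all(reference %in% sample_ids)) return(reference)
  if (!is.null(groups) && length(reference) == 1L &&
      any(groups == reference)) return(sample_ids[groups == reference])
  stop("reference '", paste(reference, collapse = ", "),
       "' matches neither sample IDs nor a group label")
}

#' Filter peptides by allowed modifications
#'
#' Retains a peptide only when every modification on it belongs to the
#' allowed set; by default methionine oxidation and cysteine
#' carbamidomethylation (chemical artifacts of sample handling) are allowed
#' and everything else — e.g. phosphorylation — disqualifies the peptide,
#' since biologically modified species must not enter the unmodified-peptide
#' regression. Matching is by configurable name patterns because search
#' engines spell modifications differently.
#'
#' @param annotations Data frame with columns `protein`, `peptide` and
#'   `modifications` (free-text, multiple modifications separated by `;` or
#'   `,`; empty/`NA`/"unmodified" means none).
#' @param allowed_patterns Case-insensitive regular expressions; a
#'   modification token is allowed when any pattern matches it.
#' @return Character vector of retained `protein::peptide` keys.
#' @export
filter_allowed_modifications <- function(
    annotations,
    allowed_patterns = c("oxidation", "carbamidomethyl")) {
  need <- c("protein", "peptide", "modifications")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  ok <- vapply(annotations$modifications, function(m) {
    if (is.na(m) || !nzchar(trimws(m))) return(TRUE)
    if (tolower(trimws(m)) %in% c("unmodified", "none")) return(TRUE)
    tokens <- trimws(strsplit(m, "[;,]")[[1]])
    tokens <- tokens[nzchar(tokens)]
    all(vapply(tokens, function(t)
      any(vapply(allowed_patterns, grepl, logical(1), x = t,
                 ignore.case = TRUE)), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  message("filter_allowed_modifications: retained ", sum(ok), " of ",
          length(ok), " peptides")
  paste(annotations$protein[ok], annotations$peptide[ok], sep = "::")
}

# ---- output writers ---------------------------------------------------------

write_matrix_csv <- function(mat, table, path) {
  df <- data.frame(sample = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$groups) &&
      all(rownames(mat) %in% table$sample_ids)) {
    df$group <- table$groups[match(rownames(mat), table$sample_ids)]
  }
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Write the result files of an analysis
#'
#' Produces the five standard CSV outputs under
#' `<output_dir>/<base>_RM_scores.csv`, `_raw_scores.csv`,
#' `_removed_peptides.csv`, `_diagnostics.csv` and `_calls.csv`.
#' Score files have one row per sample; flagged peptide cells are empty in
#' the RM file and listed per (protein, sample, peptide) in the
#' removed-peptides file, which preserves their raw scores.
#'
#' @param results A single `flq_result`/`flq_super_result` or a list of
#'   them (one per protein or group).
#' @param table The [intensity_table()] the results came from (supplies
#'   group labels for the score files).
#' @param output_dir Directory to write into (created if needed).
#' @param base File-name prefix.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_results <- function(results, table, output_dir, base = "flexiquantLF") {
  if (inherits(results, "flq_result") ||
      inherits(results, "flq_super_result")) results <- list(results)
  results <- lapply(results, function(r)
    if (inherits(r, "flq_super_result")) r$pooled else r)
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no results to write")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  rm_all <- do.call(cbind, lapply(results, `[[`, "rm_scores"))
  raw_all <- do.call(cbind, lapply(results, `[[`, "raw_scores"))
  flags_all <- do.call(cbind, lapply(results, `[[`, "flags"))
  rm_out <- rm_all
  rm_out[flags_all] <- NA_real_

  removed <- do.call(rbind, lapply(results, function(r) {
    idx <- which(r$flags, arr.ind = TRUE)
    fl <- if (nrow(idx)) data.frame(
      protein = r$diagnostics$protein[1],
      sample = rownames(r$flags)[idx[, 1]],
      peptide_key = colnames(r$flags)[idx[, 2]],
      raw_score = r$raw_scores[idx],
      reason = "raw_score_outlier", stringsAsFactors = FALSE) else NULL
    ex <- if (length(r$excluded_peptides)) data.frame(
      protein = r$diagnostics$protein[1], sample = NA_character_,
      peptide_key = r$excluded_peptides, raw_score = NA_real_,
      reason = "zero_or_missing_reference", stringsAsFactors = FALSE) else NULL
    rbind(fl, ex)
  }))
  if (is.null(removed))
    removed <- data.frame(protein = character(), sample = character(),
                          peptide_key = character(), raw_score = numeric(),
                          reason = character())
  diagnostics <- do.call(rbind, lapply(results, `[[`, "diagnostics"))
  calls <- do.call(rbind, lapply(results, `[[`, "calls"))

  paths <- c(
    rm_scores = write_matrix_csv(rm_out, table,
      file.path(output_dir, paste0(base, "_RM_scores.csv"))),
    raw_scores = write_matrix_csv(raw_all, table,
      file.path(output_dir, paste0(base, "_raw_scores.csv"))),
    removed_peptides = {
      p <- file.path(output_dir, paste0(base, "_removed_peptides.csv"))
      utils::write.csv(removed, p, row.names = FALSE, na = ""); p
    },
    diagnostics = {
      p <- file.path(output_dir, paste0(base, "_diagnostics.csv"))
      utils::write.csv(diagnostics, p, row.names = FALSE, na = ""); p
    },
    calls = {
      p <- file.path(output_dir, paste0(base, "_calls.csv"))
      utils::write.csv(calls, p, row.names = FALSE, na = ""); p
    })
  invisible(paths)
}

#' Run the full analysis pipeline on an input file
#'
#' Read, validate, filter to complete peptides, optionally collapse
#' replicates to condition medians, score every protein with enough
#' peptides (and optionally superprotein groups), and write the five output
#' CSVs. Peptide and protein attrition at each step is reported via
#' messages.
#'
#' @param input Path to the intensity table (see [read_intensity_table()]).
#' @param output_dir Output directory.
#' @param reference Reference group label or sample IDs.
#' @param layout Input layout, `"auto"`, `"wide"` or `"long"`.
#' @param config An [flq_config()].
#' @param call_sample Sample for summary calls (default last).
#' @param superprotein Optional path to a group definition CSV
#'   (see [read_superprotein_groups()]); groups are analyzed in addition to
#'   the individual proteins.
#' @param replicate_map Optional path to a CSV with columns `sample` and
#'   `condition`; replicates are collapsed to condition medians before
#'   scoring.
#' @param base Output file-name prefix (default: input file name without
#'   extension).
#' @param seed Integer seed for reproducible fits.
#' @return Named vector of output file paths, invisibly.
#' @export
run_pipeline <- function(input, output_dir, reference,
                         layout = "auto", config = flq_config(),
                         call_sample = NULL, superprotein = NULL,
                         replicate_map = NULL, base = NULL, seed = config$seed) {
  table <- read_intensity_table(input, layout, reference)
  message("read ", length(table$sample_ids), " samples x ",
          ncol(table$values), " peptides (",
          length(unique(table$proteins)), " proteins)")
  table <- filter_complete(table)
  if (!is.null(replicate_map)) {
    map <- utils::read.csv(replicate_map, stringsAsFactors = FALSE)
    table <- aggregate_replicates(table, map)
    message("collapsed replicates to ", length(table$sample_ids),
            " conditions")
  }
  if (is.null(base))
    base <- sub("\\.[^.]*$", "", basename(input))
  if (is.null(seed)) seed <- sample.int(1000000L, 1L)
  seed <- as.numeric(seed)

  proteins <- unique(table$proteins)
  results <- list()
  for (i in seq_along(proteins)) {
    res <- withCallingHandlers(
      analyze_protein(table, proteins[i], config, call_sample,
                      seed = seed + (i - 1L) * 1000000L),
      warning = function(w) {
        message(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    if (!is.null(res)) results[[proteins[i]]] <- res
  }
  if (!is.null(superprotein)) {
    groups <- read_superprotein_groups(superprotein)
    for (g in names(groups)) {
      results[[paste0("superprotein_", g)]] <- analyze_superprotein(
        table, groups[[g]]$members, config, call_sample,
        seed = seed + 900000000L)
    }
  }
  if (!length(results))
    stop("no protein passed the minimum-peptide requirement (",
         config$min_peptides, "); consider a superprotein group")
  paths <- write_results(results, table, output_dir, base)
  message("wrote ", length(paths), " files to ", output_dir)
  invisible(paths)
}
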