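#' Pooled "superprotein" analysis of co-stoichiometric proteins
#'
#' Proteins known to keep fixed stoichiometry within a complex can be pooled
#' and analyzed as one virtual protein, making members with fewer than
#' `min_peptides` peptides analyzable. Regression and raw scores are
#' computed once per sample on the pooled peptide set; raw scores are then
#' split by parent protein and the outlier gate plus top-3 RM scaling run
#' independently within each member's partition. Members whose partition
#' keeps fewer than three unflagged peptides receive raw scores but no RM
#' scores (reported `not_evaluated`).
#'
#' @param table An [intensity_table()], complete for the member proteins.
#' @param members Character vector of pooled protein identifiers. Proteins
#'   with known abundance changes must be left out by the caller.
#' @param config An [flq_config()].
#' @param call_sample Sample at which per-peptide summary calls are made
#'   (default last sample).
#' @param seed Integer seed; overrides `config$seed` when given.
#' @return A list of class `flq_super_result`: `pooled` (an `flq_result`
#'   over the pooled peptide set, with per-protein outlier gating and RM
#'   scaling already applied) and `per_protein`, a named list mapping each
#'   member to its slice of the scores and calls.
#' @export
analyze_superprotein <- function(table, members, config = flq_config(),
                                 call_sample = NULL, seed = config$seed) {
  members <- unique(as.character(members))
  if (!length(members)) stop("empty superprotein group")
  missing <- setdiff(members, table$proteins)
  if (length(missing))
    stop("superprotein member(s) not in table: ",
         paste(missing, collapse = ", "))

  refs <- lapply(members, function(p) median_reference_vector(table, p))
  cols <- unlist(lapply(refs, `[[`, "columns"))
  x <- unlist(lapply(refs, `[[`, "x"))
  excluded <- unlist(lapply(refs, `[[`, "excluded"))
  owner <- rep(members, vapply(refs, function(r) length(r$x), integer(1)))
  n <- length(x)
  if (n < config$min_peptides)
    stop("pooled group has ", n, " usable peptides (< ",
         config$min_peptides, ")")
  samples <- table$sample_ids
  if (is.null(call_sample)) call_sample <- samples[length(samples)]
  if (!call_sample %in% samples)
    stop("call sample '", call_sample, "' not in table")
  if (is.null(seed)) seed <- sample.int(1000000L, 1L)
  seed <- as.numeric(seed)

  pep_keys <- colnames(table$values)[cols]
  nsamp <- length(samples)
  raw <- rm <- matrix(NA_real_, nsamp, n, dimnames = list(samples, pep_keys))
  flags <- matrix(FALSE, nsamp, n, dimnames = list(samples, pep_keys))
  diag_rows <- list()
  for (i in seq_len(nsamp)) {
    y <- table$values[i, cols]
    fit <- best_of_k_fits(x, y, config, seed = seed + (i - 1L) * 10000L)
    s <- raw_scores(x, y, fit$slope)
    raw[i, ] <- s
    # outlier gate and RM scaling per member protein
    for (p in members) {
      j <- which(owner == p)
      gate <- flag_high_outliers(s[j])
      flags[i, j] <- gate$flags
      scaling <- NA_real_
      if (sum(!gate$flags) >= 3L) {
        rmres <- rm_scores(s[j], gate$flags)
        rm[i, j] <- rmres$rm
        scaling <- rmres$scaling_factor
      }
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        protein = p, sample = samples[i], slope = fit$slope,
        r_squared = fit$r_squared, n_inliers = sum(fit$inlier_mask),
        residual_threshold = fit$residual_threshold,
        outlier_threshold = gate$threshold, scaling_factor = scaling,
        initiation_index = fit$initiation_index, stringsAsFactors = FALSE)
    }
  }
  diag <- do.call(rbind, diag_rows)

  rm_call <- rm[call_sample, ]
  category <- classify_rm(unname(rm_call), config)
  scal_call <- diag$scaling_factor[diag$sample == call_sample]
  not_eval <- members[is.na(scal_call)]
  category[owner %in% not_eval] <- "not_evaluated"
  calls <- data.frame(protein = owner, peptide = table$peptides[cols],
                      peptide_key = pep_keys, rm_score = unname(rm_call),
                      category = category, stringsAsFactors = FALSE)

  pooled <- structure(
    list(protein = paste(members, collapse = "+"), raw_scores = raw,
         rm_scores = rm, modification_extent = 1 - rm, flags = flags,
         diagnostics = diag, calls = calls, excluded_peptides = excluded,
         call_sample = call_sample),
    class = "flq_result")
  per_protein <- lapply(stats::setNames(members, members), function(p) {
    j <- which(owner == p)
    list(protein = p,
         raw_scores = raw[, j, drop = FALSE],
         rm_scores = rm[, j, drop = FALSE],
         flags = flags[, j, drop = FALSE],
         calls = calls[calls$protein == p, , drop = FALSE],
         evaluated = !(p %in% not_eval))
  })
  structure(list(pooled = pooled, per_protein = per_protein,
                 members = members),
            class = "flq_super_result")
}

#' Read a superprotein group definition file
#'
#' CSV with columns `group_id`, `protein_id`, `role` (one of `member`,
#' `excluded`). Excluded proteins (e.g. complex members with known abundance
#' changes) are recorded but not pooled.
#'
#' @param path Path to the CSV file.
#' @return Named list of groups, each with `members` and `excluded`.
#' @export
read_superprotein_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "protein_id", "role")
  if (!all(need %in% names(df)))
    stop("superprotein file needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$role), c("member", "excluded"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  lapply(split(df, df$group_id), function(g)
    list(members = g$protein_id[g$role == "member"],
         excluded = g$protein_id[g$role == "excluded"]))
}
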