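#' Analysis configuration
#'
#' Bundles the robust-regression and classification parameters. Defaults are
#' the method's standard settings: up to 1000 RANSAC trials per initiation,
#' candidate subsets of half the peptides, 30 initiations with the best model
#' chosen by coefficient of determination, RM-score class cutoffs 0.5/0.6,
#' and a minimum of five peptides per protein.
#'
#' @param max_trials Maximum random subset draws per RANSAC initiation.
#' @param min_samples_fraction Fraction of peptides drawn per trial (the
#'   candidate subset size is `ceiling(fraction * n)`).
#' @param n_initiations Number of independent RANSAC initiations; the fit
#'   with the highest r-squared wins.
#' @param cutoff_likely RM score below which a peptide is called likely
#'   differentially modified.
#' @param cutoff_possibly RM score at or above which a peptide is called
#'   likely **not** differentially modified; scores in
#'   `[cutoff_likely, cutoff_possibly)` are called possibly modified.
#' @param min_peptides Minimum complete peptides required to analyze a
#'   protein (at least 3, so the top-3 scaling median exists).
#' @param seed Optional integer seed making the whole analysis reproducible.
#' @return A list of class `flq_config`.
#' @export
flq_config <- function(max_trials = 1000L, min_samples_fraction = 0.5,
                       n_initiations = 30L, cutoff_likely = 0.5,
                       cutoff_possibly = 0.6, min_peptides = 5L,
                       seed = NULL) {
  stopifnot(max_trials >= 1, n_initiations >= 1,
            min_samples_fraction > 0, min_samples_fraction <= 1,
            min_peptides >= 3)
  if (!(cutoff_likely < cutoff_possibly))
    stop("'cutoff_likely' must be below 'cutoff_possibly'")
  structure(list(max_trials = as.integer(max_trials),
                 min_samples_fraction = min_samples_fraction,
                 n_initiations = as.integer(n_initiations),
                 cutoff_likely = cutoff_likely,
                 cutoff_possibly = cutoff_possibly,
                 min_peptides = as.integer(min_peptides),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "flq_config")
}

#' Unscaled median absolute deviation
#'
#' `median(|v - median(v)|)` without the 1.4826 normal-consistency factor.
#' This is the deviation unit used both for the RANSAC residual threshold
#' (squared) and for the high-side raw-score outlier gate.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Non-negative scalar.
#' @export
mad_raw <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("mad_raw: no finite values")
  stats::mad(values, constant = 1)
}

#' Least-squares slope through the origin
#'
#' Fits `y = beta * x` (no intercept) on a subset of points:
#' `beta = sum(x*y) / sum(x^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param subset Integer indices of the points to fit on (default all).
#' @return The slope `beta`.
#' @export
fit_origin_ols <- function(x, y, subset = seq_along(x)) {
  if (length(subset) < 2L) stop("origin fit needs at least two points")
  xs <- x[subset]; ys <- y[subset]
  sxx <- sum(xs * xs)
  if (sxx == 0) stop("degenerate fit: all x in subset are zero")
  sum(xs * ys) / sxx
}

# Coefficient of determination of the origin-line y = beta*x, evaluated on
# the given points: 1 - SS_res / SS_tot with SS_tot about mean(y).
r_squared <- function(x, y, beta, subset = seq_along(x)) {
  xs <- x[subset]; ys <- y[subset]
  ss_res <- sum((ys - beta * xs)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Single RANSAC fit of sample against reference intensities
#'
#' One robust-regression run: for up to `max_trials` trials a random subset
#' of `ceiling(min_samples_fraction * n)` peptides is drawn, an origin-OLS
#' slope fitted to the draw, and peptide j counted as an inlier when its
#' squared residual is at most `mad_raw(y)^2` (equivalently
#' `|y_j - beta*x_j| <= mad_raw(y)`). The candidate with the most inliers
#' wins (ties broken by higher r-squared on the candidate's inliers); the
#' final slope is an origin-OLS refit on the winning inlier set and the
#' reported r-squared is evaluated on **all** peptides, so competing
#' initiations are compared on identical data.
#'
#' @param x Strictly positive reference intensities.
#' @param y Sample intensities, same length as `x`.
#' @param config An [flq_config()].
#' @param seed Integer seed; the run is deterministic given `seed`.
#' @return A list of class `flq_fit`: `slope`, `inlier_mask`, `r_squared`,
#'   `residual_threshold` (the squared threshold), `initiation_index`.
#' @export
ransac_fit <- function(x, y, config = flq_config(), seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("reference intensities must be strictly positive")
  if (!is.null(seed))
    set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  m <- max(2L, as.integer(ceiling(config$min_samples_fraction * n)))
  if (m > n) stop("candidate subset larger than peptide count")
  thr <- mad_raw(y)  # inlier iff |residual| <= thr, i.e. residual^2 <= thr^2

  n_trials <- config$max_trials
  # draw all candidate subsets at once: random keys per (peptide, trial),
  # the m smallest keys of each column form that trial's subset
  keys <- matrix(stats::runif(n * n_trials), n)
  o <- order(col(keys), keys)
  idx <- matrix((o - 1L) %% n + 1L, n)[seq_len(m), , drop = FALSE]
  xi <- matrix(x[idx], nrow = m)
  yi <- matrix(y[idx], nrow = m)
  betas <- colSums(xi * yi) / colSums(xi * xi)
  resid_ok <- abs(y - outer(x, betas)) <= thr   # n x trials
  counts <- colSums(resid_ok)

  best_count <- max(counts)
  if (best_count < 2L)
    stop("RANSAC failed: no trial produced at least two inliers")
  tied <- which(counts == best_count)
  if (length(tied) > 1L) {
    # identical inlier sets give identical refits; score each distinct set once
    tied_masks <- resid_ok[, tied, drop = FALSE]
    mask_key <- if (n <= 50) colSums(tied_masks * 2^(seq_len(n) - 1))
                else apply(tied_masks, 2L, paste, collapse = "")
    first_of <- tied[!duplicated(mask_key)]
    r2_distinct <- vapply(first_of, function(t)
      r_squared(x, y, betas[t], which(resid_ok[, t])), numeric(1))
    winner <- first_of[which.max(r2_distinct)]
  } else {
    winner <- tied
  }
  inliers <- which(resid_ok[, winner])
  slope <- fit_origin_ols(x, y, inliers)
  # refit may move individual points across the threshold; the consensus
  # mask from the winning trial is retained, as in the classic algorithm
  structure(list(slope = slope,
                 inlier_mask = resid_ok[, winner],
                 r_squared = r_squared(x, y, slope),
                 residual_threshold = thr^2,
                 initiation_index = NA_integer_),
            class = "flq_fit")
}

#' Best of K independent RANSAC initiations
#'
#' Runs [ransac_fit()] `config$n_initiations` times with deterministic
#' sub-seeds (`seed + k - 1` for initiation k) and returns the fit with the
#' highest r-squared; ties go to the earliest initiation. Multiple
#' initiations suppress the run-to-run ambiguity a single consensus search
#' can show when two peptide subsets support different slopes.
#'
#' @inheritParams ransac_fit
#' @return An `flq_fit` with `initiation_index` set (1-based).
#' @export
best_of_k_fits <- function(x, y, config = flq_config(), seed = NULL) {
  if (is.null(seed)) seed <- sample.int(1000000L, 1L)
  seed <- as.numeric(seed)
  best <- NULL
  failures <- character(0)
  for (k in seq_len(config$n_initiations)) {
    fit <- tryCatch(ransac_fit(x, y, config, seed = seed + k - 1L),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$r_squared > best$r_squared) {
      fit$initiation_index <- k
      best <- fit
    }
  }
  if (is.null(best))
    stop("all ", config$n_initiations, " RANSAC initiations failed: ",
         failures[1])
  best
}
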