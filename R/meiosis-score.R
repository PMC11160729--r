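# Depth-normalize to 1e4 counts per cell and log1p. Cells with zero total
# are left at zero (their normalized profile is all-zero, not NaN).
normalize_log1p <- function(counts, scale_to = 1e4) {
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  log1p(as.matrix(counts) / totals * scale_to)
}

# z-score columns; zero-variance columns contribute 0 by convention.
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  z <- sweep(sweep(m, 2, mu, "-"), 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  z
}

#' Score cells on a meiosis gene panel
#'
#' Counts are depth-normalized (counts x 1e4 / cell total) and
#' log1p-transformed; each panel gene is z-scored across cells; a cell's
#' score is the sum of its panel z-scores divided by sqrt(panel size), so
#' under independent null genes the score has mean 0 and unit variance and
#' the sigma threshold has its standard-normal meaning. Cells with
#' score > `threshold_sigma` are called meiotic.
#'
#' The "sigma" unit is the theoretical scale of the standardized score, not
#' the empirical SD of observed scores (which true meiotic cells inflate);
#' the empirical SD is also reported.
#'
#' @param counts Sparse or dense cells x genes count matrix with dimnames.
#' @param panel Character vector of panel genes; all must be present in
#'   `counts` (missing genes raise an error naming them). Defaults to
#'   [default_meiosis_panel()].
#' @param threshold_sigma Calling threshold on the score (default 4).
#' @return A `meiosis_score_result`: list with `scores` (data.frame `cell`,
#'   `score`, `is_meiotic`) and `summary` (list with `n_cells`,
#'   `n_exceeding`, `expected_exceeding_gaussian`, `threshold_sigma`,
#'   `empirical_sd`).
#' @export
#' @examples
#' sim <- simulate_count_matrix(sim_config(n_cells = 200, n_genes = 200,
#'                                         panel_mean_shift = 4))
#' res <- score_cells(sim$counts)
#' res$summary$n_exceeding
score_cells <- function(counts, panel = default_meiosis_panel(),
                        threshold_sigma = 4) {
  if (length(panel) == 0L || anyDuplicated(panel))
    ms_stop("invalid `panel`: must be non-empty with no duplicates")
  missing <- setdiff(panel, colnames(counts))
  if (length(missing))
    ms_stop("panel genes missing from matrix: %s",
            paste(missing, collapse = ", "))
  n <- nrow(counts)
  k <- length(panel)
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  sub <- as.matrix(counts[, panel, drop = FALSE])
  ln <- log1p(sub / totals * 1e4)
  z <- zscore_cols(ln)
  score <- rowSums(z) / sqrt(k)
  res <- data.frame(cell = if (is.null(rownames(counts)))
    sprintf("cell%06d", seq_len(n)) else rownames(counts),
    score = score, is_meiotic = score > threshold_sigma,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    scores = res,
    summary = list(
      n_cells = n,
      n_exceeding = sum(res$is_meiotic),
      expected_exceeding_gaussian =
        expected_exceedances(n, threshold_sigma)$expected,
      threshold_sigma = threshold_sigma,
      empirical_sd = if (n > 1) sd(score) else NA_real_)),
    class = "meiosis_score_result")
}

#' @export
print.meiosis_score_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "meiosis_score_result: %d cells, %d > %gsigma (%.2f expected under Gaussian null)\n",
    s$n_cells, s$n_exceeding, s$threshold_sigma,
    s$expected_exceeding_gaussian))
  invisible(x)
}

#' Expected score exceedances under the Gaussian null
#'
#' Number of cells expected above a sigma threshold if scores were standard
#' normal: `n_cells * pnorm(t, lower.tail = FALSE)`.
#'
#' @param n_cells Number of cells.
#' @param threshold_sigma Threshold in sigma units.
#' @return List with `expected` (real) and `rounded` (nearest integer).
#' @export
#' @examples
#' expected_exceedances(646493, 4)
expected_exceedances <- function(n_cells, threshold_sigma) {
  check_count(n_cells, "n_cells")
  if (!is.finite(threshold_sigma))
    ms_stop("invalid `threshold_sigma`: must be finite")
  e <- n_cells * pnorm(threshold_sigma, lower.tail = FALSE)
  list(expected = e, rounded = round(e))
}

#' Permutation null for the panel score
#'
#' Draws random gene panels of the given size from all expressed genes
#' (total count > 0), recomputes the score for every cell, and reports the
#' empirical fraction of (cell, permutation) scores exceeding each
#' threshold, with a binomial normal-approximation confidence interval.
#' This is the empirical check of the random-expression Gaussian null.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param panel_size Number of genes per random panel.
#' @param n_perm Number of random panels (> 0, else error).
#' @param seed Integer seed.
#' @param thresholds Sigma thresholds at which to evaluate the tail.
#' @param conf Confidence level of the binomial CI.
#' @return data.frame with columns `threshold`, `tail`, `gaussian_tail`,
#'   `se`, `lower`, `upper`, `n_draws`.
#' @export
permutation_null <- function(counts, panel_size = 19L, n_perm = 200L,
                             seed = 1L, thresholds = c(1, 2, 3),
                             conf = 0.95) {
  if (n_perm < 1) ms_stop("no_permutations: `n_perm` must be >= 1")
  expressed <- which(Matrix::colSums(counts) > 0)
  if (length(expressed) < panel_size)
    ms_stop("fewer expressed genes (%d) than `panel_size` (%d)",
            length(expressed), panel_size)
  ln <- normalize_log1p(counts[, expressed, drop = FALSE])
  z <- zscore_cols(ln)
  n <- nrow(counts)
  withr::with_seed(as.integer(seed), {
    exceed <- matrix(0, length(thresholds), n_perm)
    for (p in seq_len(n_perm)) {
      idx <- sample(ncol(z), panel_size)
      s <- rowSums(z[, idx, drop = FALSE]) / sqrt(panel_size)
      exceed[, p] <- vapply(thresholds, function(t) sum(s > t), numeric(1))
    }
    n_draws <- n * n_perm
    tail <- rowSums(exceed) / n_draws
    se <- sqrt(tail * (1 - tail) / n_draws)
    zq <- -qnorm((1 - conf) / 2)
    data.frame(threshold = thresholds, tail = tail,
               gaussian_tail = pnorm(thresholds, lower.tail = FALSE),
               se = se, lower = pmax(0, tail - zq * se),
               upper = pmin(1, tail + zq * se), n_draws = n_draws)
  })
}
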