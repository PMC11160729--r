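#' Assign expressed factor barcodes to cells
#'
#' A factor is assigned to a cell iff its captured UMI support is at least
#' `min_umi` (default 1: a single expressed barcode suffices). Coverage is
#' the fraction of profiled cells with at least one assigned factor.
#'
#' @param capture data.frame with columns `cell`, `factor`, `umi` (e.g. from
#'   [simulate_capture()] or a capture-counts CSV).
#' @param cells Character vector of all profiled cell identifiers (the
#'   coverage denominator). Cells absent from `capture` count as uncovered.
#' @param min_umi Minimum UMI support for an assignment.
#' @return A `cell_barcode_assignment`: list with `assignments` (filtered
#'   long data.frame), `cells`, `coverage`.
#' @export
#' @examples
#' cap <- data.frame(cell = c("c1", "c1", "c2"),
#'                   factor = c("BCL2", "BOLL", "BCL2"), umi = c(3, 1, 2))
#' assign_barcodes(cap, cells = c("c1", "c2", "c3"))$coverage
assign_barcodes <- function(capture, cells, min_umi = 1L) {
  stopifnot(all(c("cell", "factor", "umi") %in% names(capture)))
  check_count(min_umi, "min_umi")
  keep <- capture$umi >= min_umi
  asg <- capture[keep, c("cell", "factor", "umi"), drop = FALSE]
  extra <- setdiff(asg$cell, cells)
  if (length(extra))
    ms_stop("capture table contains cells not in `cells`: %s",
            paste(head(extra, 3), collapse = ", "))
  structure(list(assignments = asg,
                 cells = as.character(cells),
                 coverage = length(unique(asg$cell)) / max(1L, length(cells))),
            class = "cell_barcode_assignment")
}

#' @export
print.cell_barcode_assignment <- function(x, ...) {
  cat(sprintf(
    "cell_barcode_assignment: %d cells, coverage %.3f, %d assignments\n",
    length(x$cells), x$coverage, nrow(x$assignments)))
  invisible(x)
}

# Two-sided exact p for a 2x2 table conditioned on both margins: sum of
# hypergeometric point probabilities <= the observed one (with the usual
# relative tolerance guarding float ties).
exact_2x2_p <- function(a, b, c, d) {
  m <- a + b            # meiotic cells
  nn <- c + d           # non-meiotic cells
  k <- a + c            # cells with the factor
  support <- max(0L, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Factor overrepresentation in meiotic vs pre-meiotic cells
#'
#' Cells with at least one assigned barcode are cross-tabulated per factor
#' into a 2x2 table (meiotic/non-meiotic x factor present/absent). P-values
#' are two-sided exact conditional tests on the table; odds ratios are
#' sample ORs with a Haldane 0.5 correction when any cell of the table is
#' zero; q-values are Benjamini-Hochberg across factors. Factors are ranked
#' by (q ascending, odds ratio descending, name ascending).
#'
#' @param assignment A [assign_barcodes()] result.
#' @param meiotic_labels Named logical vector (cell -> is meiotic) covering
#'   all assigned cells.
#' @return An `overrepresentation_result`: data.frame with columns `factor`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`, `rank`, ordered
#'   by rank.
#' @export
overrepresentation <- function(assignment, meiotic_labels) {
  stopifnot(inherits(assignment, "cell_barcode_assignment"))
  asg <- assignment$assignments
  cells <- unique(asg$cell)
  lab <- meiotic_labels[cells]
  if (any(is.na(lab)))
    ms_stop("missing meiotic labels for %d assigned cell(s)", sum(is.na(lab)))
  n_mei <- sum(lab)
  n_non <- sum(!lab)
  if (n_mei == 0L || n_non == 0L)
    ms_stop("degenerate_contrast: need >= 1 meiotic and >= 1 non-meiotic %s",
            "cell among assigned cells")
  factors <- sort(unique(asg$factor))
  has <- lapply(split(asg$cell, asg$factor), unique)
  rows <- lapply(factors, function(f) {
    a <- sum(lab[has[[f]]])
    c_ <- length(has[[f]]) - a
    b <- n_mei - a
    d <- n_non - c_
    or <- if (a == 0L || b == 0L || c_ == 0L || d == 0L)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(factor = f, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_value = exact_2x2_p(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  ord <- order(res$q_value, -res$odds_ratio, res$factor)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("overrepresentation_result", "data.frame")
  res
}

#' Select the top-ranked factors
#'
#' @param results An [overrepresentation()] result.
#' @param k Number of factors to keep; values above the number of factors
#'   are clamped with a warning.
#' @return Character vector of factor names in rank order.
#' @export
select_top <- function(results, k) {
  check_count(k, "k")
  if (k > nrow(results)) {
    ms_warn("k = %d exceeds the %d available factors; returning all",
            k, nrow(results))
    k <- nrow(results)
  }
  results$factor[seq_len(k)]
}
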