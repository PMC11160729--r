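# --- nearest-centroid label transfer, proportion tables, onset detection ---

#' Build reference centroids from a labelled expression matrix
#'
#' Per-type mean of depth-normalized log1p expression. Types with fewer than
#' `min_cells` reference cells are flagged (and reported in the result), not
#' dropped.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param labels Named character vector (cell -> type) or vector aligned
#'   with matrix rows.
#' @param min_cells Flagging threshold for sparsely represented types.
#' @return A `reference_centroids`: list with `centroids` (types x genes
#'   matrix of mean log-normalized expression), `n_cells`, `flagged`,
#'   `genes`.
#' @export
build_reference <- function(counts, labels, min_cells = 10L) {
  if (!is.null(names(labels))) {
    miss <- setdiff(rownames(counts), names(labels))
    if (length(miss))
      ms_stop("labels missing for %d cell(s)", length(miss))
    labels <- labels[rownames(counts)]
  }
  if (length(labels) != nrow(counts))
    ms_stop("`labels` must cover every cell of the matrix")
  ln <- normalize_log1p(counts)
  types <- sort(unique(as.character(labels)))
  centroids <- do.call(rbind, lapply(types, function(ty)
    colMeans(ln[labels == ty, , drop = FALSE])))
  rownames(centroids) <- types
  n_cells <- vapply(types, function(ty) sum(labels == ty), integer(1))
  structure(list(centroids = centroids,
                 n_cells = n_cells,
                 flagged = names(n_cells)[n_cells < min_cells],
                 genes = colnames(counts)),
            class = "reference_centroids")
}

#' @export
print.reference_centroids <- function(x, ...) {
  cat("reference_centroids:", nrow(x$centroids), "types x",
      ncol(x$centroids), "genes\n")
  if (length(x$flagged))
    cat("  flagged (<", min(x$n_cells[x$flagged]), "cells):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

row_standardize <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  zero <- sdv == 0
  sdv[zero] <- 1
  z <- (m - mu) / sdv
  z[zero, ] <- 0
  z
}

#' Transfer cell-type labels by nearest centroid
#'
#' Each query cell is assigned the type of its most similar reference
#' centroid over the shared gene set, by Pearson correlation (default) or
#' cosine similarity of log-normalized expression. Ties break by type name
#' ascending; cells with zero variance (e.g. all-zero cells) get similarity
#' 0 and the alphabetically first type.
#'
#' @param query Cells x genes count matrix with dimnames.
#' @param ref A [build_reference()] result.
#' @param metric `"pearson"` or `"cosine"`.
#' @param min_shared_genes Warn when fewer genes are shared.
#' @return data.frame with columns `cell`, `type`, `similarity`.
#' @export
annotate_cells <- function(query, ref, metric = c("pearson", "cosine"),
                           min_shared_genes = 200L) {
  metric <- match.arg(metric)
  stopifnot(inherits(ref, "reference_centroids"))
  shared <- intersect(colnames(query), ref$genes)
  if (!length(shared)) ms_stop("no genes shared between query and reference")
  if (length(shared) < min_shared_genes)
    ms_warn("only %d genes shared between query and reference",
            length(shared))
  q <- normalize_log1p(query[, shared, drop = FALSE])
  cmat <- ref$centroids[, shared, drop = FALSE]
  g <- length(shared)
  if (metric == "pearson") {
    qz <- row_standardize(q)
    cz <- row_standardize(cmat)
    sim <- qz %*% Matrix::t(cz) / (g - 1)  # sample-sd standardization
  } else {
    qn <- sqrt(rowSums(q^2)); qn[qn == 0] <- 1
    cn <- sqrt(rowSums(cmat^2)); cn[cn == 0] <- 1
    sim <- (q / qn) %*% Matrix::t(cmat / cn)
  }
  sim <- as.matrix(sim)
  # ties (and degenerate all-equal rows) resolve to the first type, and
  # types are stored in ascending name order
  best <- max.col(sim, ties.method = "first")
  data.frame(cell = rownames(q),
             type = rownames(cmat)[best],
             similarity = sim[cbind(seq_len(nrow(sim)), best)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split cell-type proportions into common and rare tables
#'
#' Input is either a long count table (`day`, `line`, `type` or `stage`,
#' `count`) or per-observation rows (`day`, `line`, `type`) that are tallied
#' first. Proportions are computed within each (day, line); a type is
#' "common" iff its overall mean proportion across (day, line) groups is
#' strictly greater than `abundance_cutoff` (a type at exactly the cutoff is
#' rare).
#'
#' @param x data.frame as above.
#' @param abundance_cutoff Common/rare split point on the overall mean
#'   proportion (default 0.05).
#' @return List with `common` and `rare` long-format data.frames (`day`,
#'   `line`, `type`, `count`, `proportion`) and `overall` (per-type mean
#'   proportion with the common flag).
#' @export
proportion_table <- function(x, abundance_cutoff = 0.05) {
  if ("stage" %in% names(x) && !"type" %in% names(x))
    names(x)[names(x) == "stage"] <- "type"
  need <- c("day", "line", "type")
  if (!all(need %in% names(x)))
    ms_stop("need columns %s", paste(need, collapse = ", "))
  if (!"count" %in% names(x)) {
    x <- as.data.frame(table(day = x$day, line = x$line, type = x$type),
                       stringsAsFactors = FALSE)
    names(x)[names(x) == "Freq"] <- "count"
    x$day <- as.integer(x$day)
  }
  if (any(x$count < 0)) ms_stop("counts must be non-negative")
  agg <- stats::aggregate(count ~ day + line + type, data = x, FUN = sum)
  grp_tot <- stats::aggregate(count ~ day + line, data = agg, FUN = sum)
  names(grp_tot)[3] <- "total"
  agg <- merge(agg, grp_tot, by = c("day", "line"))
  agg <- agg[agg$total > 0, , drop = FALSE]
  agg$proportion <- agg$count / agg$total
  agg$total <- NULL
  overall <- stats::aggregate(proportion ~ type, data = agg, FUN = mean)
  names(overall)[2] <- "mean_proportion"
  overall$common <- overall$mean_proportion > abundance_cutoff
  common_types <- overall$type[overall$common]
  agg <- agg[order(agg$day, agg$line, agg$type), , drop = FALSE]
  rownames(agg) <- NULL
  list(common = agg[agg$type %in% common_types, , drop = FALSE],
       rare = agg[!agg$type %in% common_types, , drop = FALSE],
       overall = overall)
}

#' Detect the onset day of a meiotic stage
#'
#' The smallest day at which at least `min_cells` cells of the stage are
#' seen in at least `min_replicates` lines; `NA` when never satisfied.
#'
#' @param timecourse data.frame with columns `day`, `line`, `stage` (or
#'   `type`), `count`.
#' @param stage Stage name to query.
#' @param min_cells Minimum per-line cell count.
#' @param min_replicates Minimum number of lines meeting `min_cells`.
#' @return Integer day, or `NA_integer_`.
#' @export
#' @examples
#' tc <- simulate_timecourse(seed = 1)
#' detect_onset(tc, "leptotene")
detect_onset <- function(timecourse, stage, min_cells = 1L,
                         min_replicates = 1L) {
  x <- timecourse
  if ("type" %in% names(x) && !"stage" %in% names(x))
    names(x)[names(x) == "type"] <- "stage"
  stopifnot(all(c("day", "line", "stage", "count") %in% names(x)))
  x <- x[x$stage == stage, , drop = FALSE]
  if (!nrow(x)) return(NA_integer_)
  hits <- stats::aggregate(count ~ day, data = x,
                           FUN = function(v) sum(v >= min_cells))
  ok <- hits$day[hits$count >= min_replicates]
  if (!length(ok)) return(NA_integer_)
  as.integer(min(ok))
}
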