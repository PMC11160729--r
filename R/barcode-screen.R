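#' Sample x factor barcode count table
#'
#' Container for bulk barcode counts with sample roles.
#'
#' @param counts Numeric matrix, samples x factors, non-negative integers,
#'   with dimnames.
#' @param roles Named character vector mapping each sample to `"sorted"` or
#'   `"unsorted"`.
#' @return A `barcode_count_table` object.
#' @export
barcode_count_table <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ms_stop("`counts` must have sample rownames and factor colnames")
  if (any(counts < 0) || any(counts != floor(counts)))
    ms_stop("`counts` must be non-negative integers")
  roles <- roles[rownames(counts)]
  if (any(is.na(roles)) || !all(roles %in% c("sorted", "unsorted")))
    ms_stop("`roles` must assign 'sorted' or 'unsorted' to every sample")
  structure(list(counts = counts, roles = roles),
            class = "barcode_count_table")
}

#' @export
print.barcode_count_table <- function(x, ...) {
  cat("barcode_count_table:", nrow(x$counts), "samples x",
      ncol(x$counts), "factors (",
      sum(x$roles == "sorted"), "sorted /",
      sum(x$roles == "unsorted"), "unsorted )\n")
  invisible(x)
}

#' Read or write a barcode whitelist TSV
#'
#' The TSV has columns `barcode` and `factor`. On read, barcode uniqueness is
#' enforced and a warning is issued if any pair of barcodes is closer than
#' Hamming distance 3 (single-mismatch correction would then be ambiguous).
#'
#' @param path TSV path.
#' @return `read_whitelist()` returns a `barcode_whitelist` data.frame.
#' @export
read_whitelist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "factor") %in% names(df)))
    ms_stop("whitelist must have columns 'barcode' and 'factor'")
  if (anyDuplicated(df$barcode))
    ms_stop("duplicate barcode sequences in whitelist")
  if (nrow(df) > 1) {
    dmin <- min(vapply(seq_len(nrow(df) - 1), function(i)
      min(hamming(df$barcode[i], df$barcode[(i + 1):nrow(df)])), numeric(1)))
    if (dmin < 3)
      ms_warn("whitelist min pairwise Hamming distance is %d (< 3); %s",
              dmin, "1-mismatch correction may be ambiguous")
  }
  structure(df[c("barcode", "factor")],
            class = c("barcode_whitelist", "data.frame"))
}

#' @rdname read_whitelist
#' @param whitelist A `barcode_whitelist` data.frame.
#' @export
write_whitelist <- function(whitelist, path) {
  write.table(whitelist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal 4-line FASTQ reader: returns character vector of sequences.
# Hand-rolled so malformed records can be reported with their line number.
parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    ms_stop("malformed FASTQ: %d lines is not a multiple of 4 (near line %d)",
            length(lines), length(lines))
  if (!length(lines)) return(character(0))
  hdr <- seq(1, length(lines), by = 4)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad))
    ms_stop("malformed FASTQ: record header missing '@' at line %d", bad[1])
  plus <- hdr + 2
  badp <- plus[!startsWith(lines[plus], "+")]
  if (length(badp))
    ms_stop("malformed FASTQ: separator missing '+' at line %d", badp[1])
  lines[hdr + 1]
}

#' Count factor barcodes in FASTQ reads
#'
#' A read contributes one count to a factor iff both constant flanks match
#' exactly at their expected offsets and the intervening barcode matches that
#' factor's barcode with at most `max_mismatch` substitutions. Reads matching
#' no entry, more than one entry, or with flank mismatches are tallied as
#' discarded with reason codes (`no_match`, `multi_match`, `flank_mismatch`,
#' `bad_length`).
#'
#' @param reads FASTQ file path, or a character vector of read sequences.
#' @param whitelist A `barcode_whitelist` (see [make_whitelist()],
#'   [read_whitelist()]).
#' @param flank5,flank3 Constant flanking sequences.
#' @param max_mismatch 0 or 1 barcode substitutions tolerated.
#' @param sample_id,role Sample name and role for the resulting single-sample
#'   table.
#' @return A [barcode_count_table()] with one row; attribute `discarded`
#'   holds the per-reason discard counts.
#' @export
extract_barcodes <- function(reads, whitelist,
                             flank5 = BARCODE_FLANK5,
                             flank3 = BARCODE_FLANK3,
                             max_mismatch = 1L,
                             sample_id = "sample1", role = "sorted") {
  if (!max_mismatch %in% c(0L, 1L))
    ms_stop("invalid `max_mismatch`: must be 0 or 1")
  if (length(reads) == 1L && file.exists(reads)) reads <- parse_fastq(reads)
  bl <- nchar(whitelist$barcode[1])
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  counts <- setNames(integer(nrow(whitelist)), whitelist$factor)
  discarded <- c(no_match = 0L, multi_match = 0L,
                 flank_mismatch = 0L, bad_length = 0L)

  ok_len <- nchar(reads) >= n5 + bl + n3
  discarded["bad_length"] <- sum(!ok_len)
  reads <- reads[ok_len]
  ok_flank <- substr(reads, 1, n5) == flank5 &
    substr(reads, n5 + bl + 1, n5 + bl + n3) == flank3
  discarded["flank_mismatch"] <- sum(!ok_flank)
  bcs <- substr(reads[ok_flank], n5 + 1, n5 + bl)

  exact <- match(bcs, whitelist$barcode)
  hit <- table(factor(whitelist$factor[exact[!is.na(exact)]],
                      levels = whitelist$factor))
  counts <- counts + as.integer(hit)
  if (max_mismatch == 1L && any(is.na(exact))) {
    for (b in unique(bcs[is.na(exact)])) {
      nb <- sum(bcs == b & is.na(exact))
      d <- hamming(b, whitelist$barcode)
      near <- which(d <= 1)
      if (length(near) == 1L) {
        counts[whitelist$factor[near]] <- counts[whitelist$factor[near]] + nb
      } else if (length(near) == 0L) {
        discarded["no_match"] <- discarded["no_match"] + nb
      } else {
        discarded["multi_match"] <- discarded["multi_match"] + nb
      }
    }
  } else if (any(is.na(exact))) {
    discarded["no_match"] <- discarded["no_match"] + sum(is.na(exact))
  }

  tab <- barcode_count_table(matrix(counts, nrow = 1,
                                    dimnames = list(sample_id,
                                                    names(counts))),
                             setNames(role, sample_id))
  attr(tab, "discarded") <- discarded
  tab
}

#' Combine single-sample barcode count tables
#'
#' @param ... `barcode_count_table` objects sharing the same factor columns.
#' @return A combined `barcode_count_table`.
#' @export
bind_count_tables <- function(...) {
  tabs <- list(...)
  counts <- do.call(rbind, lapply(tabs, function(t) t$counts))
  roles <- do.call(c, lapply(tabs, function(t) t$roles))
  barcode_count_table(counts, roles)
}

#' Factor enrichment in sorted vs unsorted populations
#'
#' For every (sorted, unsorted) sample pair, per-factor frequencies are
#' computed after adding `pseudocount` to each count and renormalizing, and
#' enrichment is `log2(freq_sorted / freq_unsorted)`. The summary aggregates
#' pairs per factor: mean log2 enrichment and the fraction of pairs with a
#' strictly positive sign.
#'
#' @param table A [barcode_count_table()] with at least one sorted and one
#'   unsorted sample.
#' @param pseudocount Haldane-Anscombe style pseudocount (default 0.5).
#' @return An `enrichment_result`: list with `per_pair` and `summary`
#'   data.frames.
#' @export
#' @examples
#' tab <- barcode_count_table(
#'   matrix(c(30, 10, 10, 30), 2, dimnames = list(c("s", "u"), c("A", "B"))),
#'   c(s = "sorted", u = "unsorted"))
#' enrich(tab, pseudocount = 0)$summary
enrich <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "barcode_count_table"))
  if (pseudocount < 0) ms_stop("invalid `pseudocount`: must be >= 0")
  sorted <- names(table$roles)[table$roles == "sorted"]
  unsorted <- names(table$roles)[table$roles == "unsorted"]
  if (!length(sorted) || !length(unsorted))
    ms_stop("need at least one sorted and one unsorted sample")
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    ms_stop("empty_sample: sample(s) with zero total counts: %s",
            paste(names(totals)[totals == 0], collapse = ", "))
  freq <- (table$counts + pseudocount) /
    rowSums(table$counts + pseudocount)
  pairs <- expand.grid(sorted = sorted, unsorted = unsorted,
                       stringsAsFactors = FALSE)
  per_pair <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$sorted[i]; u <- pairs$unsorted[i]
    data.frame(factor = colnames(freq), sorted_sample = s,
               unsorted_sample = u,
               freq_sorted = freq[s, ], freq_unsorted = freq[u, ],
               log2_enrichment = log2(freq[s, ] / freq[u, ]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(split(per_pair, per_pair$factor), function(d)
    data.frame(factor = d$factor[1],
               mean_log2_enrichment = mean(d$log2_enrichment),
               frac_positive = mean(d$log2_enrichment > 0),
               n_pairs = nrow(d), stringsAsFactors = FALSE)))
  summ <- summ[match(colnames(freq), summ$factor), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_pair = per_pair, summary = summ),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result over", x$summary$n_pairs[1], "sample pair(s):\n")
  print(head(x$summary[order(-x$summary$mean_log2_enrichment), ], 10))
  invisible(x)
}

#' Rank factors by sign-consistent enrichment across conditions
#'
#' Factors are ordered by the fraction of (sorted, unsorted) pairs with
#' positive log2 enrichment (descending), then by mean log2 enrichment
#' (descending), then by factor name (ascending) — an operationalization of
#' consistent enrichment across conditions.
#'
#' @param results An `enrichment_result` or a list of them (one per
#'   condition).
#' @return data.frame with columns `factor`, `frac_positive`,
#'   `mean_log2_enrichment`, `n_pairs`, `rank`, ordered best-first.
#' @export
rank_consistent <- function(results) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  pp <- do.call(rbind, lapply(results, function(r) r$per_pair))
  stats <- do.call(rbind, lapply(split(pp, pp$factor), function(d)
    data.frame(factor = d$factor[1],
               frac_positive = mean(d$log2_enrichment > 0),
               mean_log2_enrichment = mean(d$log2_enrichment),
               n_pairs = nrow(d), stringsAsFactors = FALSE)))
  ord <- order(-stats$frac_positive, -stats$mean_log2_enrichment,
               stats$factor)
  stats <- stats[ord, , drop = FALSE]
  stats$rank <- seq_len(nrow(stats))
  rownames(stats) <- NULL
  stats
}
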