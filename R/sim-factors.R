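#' Generate a barcode whitelist for a factor library
#'
#' Random fixed-length DNA barcodes, greedily accepted so that every pair is
#' at least `min_dist` substitutions apart (default 3, so single-mismatch
#' correction is unambiguous).
#'
#' @param factors Character vector of factor names.
#' @param barcode_length Barcode length in nucleotides.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @return A `barcode_whitelist`: data.frame with columns `barcode`, `factor`.
#' @export
#' @examples
#' wl <- make_whitelist(c("BCL2", "HOXB5", "BOLL"), seed = 1)
#' wl
make_whitelist <- function(factors, barcode_length = 12L, min_dist = 3L,
                           seed = 1L) {
  if (anyDuplicated(factors)) ms_stop("duplicate factor names in whitelist")
  withr::with_seed(as.integer(seed) + OP_OFFSET[["whitelist"]], {
    bases <- c("A", "C", "G", "T")
    accepted <- character(0)
    guard <- 0L
    while (length(accepted) < length(factors)) {
      cand <- paste(sample(bases, barcode_length, replace = TRUE),
                    collapse = "")
      if (!length(accepted) || all(hamming(cand, accepted) >= min_dist))
        accepted <- c(accepted, cand)
      guard <- guard + 1L
      if (guard > 1e6L) ms_stop("could not generate enough distinct barcodes")
    }
    structure(data.frame(barcode = accepted, factor = as.character(factors),
                         stringsAsFactors = FALSE),
              class = c("barcode_whitelist", "data.frame"))
  })
}

#' Simulate barcoded factor integrations and meiotic entry
#'
#' Each cell's copy count of each factor is Poisson(lambda / n_factors)
#' (equivalent to a Poisson(lambda) total assigned uniformly with
#' replacement). A cell's probability of meiotic entry is
#' `plogis(meiotic_baseline + sum of effects of its distinct factors)`.
#'
#' @param config A [sim_config()] with non-empty `factor_effects`.
#' @return A `factor_integrations` object: list with `cells`, `factors`,
#'   `copies` (sparse cells x factors copy-count matrix), `entry_prob`,
#'   `meiotic` (logical ground truth).
#' @export
#' @examples
#' fi <- simulate_factor_integrations(sim_config(n_cells = 100))
#' mean(fi$meiotic)
simulate_factor_integrations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  effects <- config$factor_effects
  if (!length(effects))
    ms_stop("invalid `factor_effects`: must be non-empty")
  n <- config$n_cells
  fac <- names(effects)
  nf <- length(fac)
  cell_ids <- sprintf("cell%06d", seq_len(n))
  with_op_seed(config$seed, "integration", {
    copies <- matrix(rpois(n * nf, lambda = config$barcode_copy_lambda / nf),
                     nrow = n, ncol = nf,
                     dimnames = list(cell_ids, fac))
    present <- copies > 0L
    eta <- config$meiotic_baseline + as.numeric(present %*% effects)
    p <- plogis(eta)
    meiotic <- runif(n) < p
    structure(list(cells = cell_ids, factors = fac,
                   copies = Matrix::Matrix(copies, sparse = TRUE),
                   entry_prob = setNames(p, cell_ids),
                   meiotic = setNames(meiotic, cell_ids)),
              class = "factor_integrations")
  })
}

#' True per-cell factor assignment as a long table
#'
#' @param integrations A `factor_integrations` object.
#' @return data.frame with columns `cell`, `factor`, `copies` (one row per
#'   integrated factor per cell).
#' @export
true_assignment <- function(integrations) {
  stopifnot(inherits(integrations, "factor_integrations"))
  tm <- as(integrations$copies, "TsparseMatrix")
  out <- data.frame(cell = integrations$cells[tm@i + 1L],
                    factor = integrations$factors[tm@j + 1L],
                    copies = as.integer(tm@x),
                    stringsAsFactors = FALSE)
  out[order(out$cell, out$factor), , drop = FALSE]
}

#' Capture efficiency needed for a target barcode coverage
#'
#' With per-factor Poisson(lambda / F) copies, a factor is present in a cell
#' with probability q = 1 - exp(-lambda / F), independently across factors,
#' so the fraction of cells with at least one captured barcode is
#' 1 - (1 - q e)^F. Solving for e gives the efficiency that reproduces a
#' desired coverage (e.g. 91 percent of cells with an expressed barcode).
#'
#' @param target_coverage Desired fraction of cells with >= 1 captured
#'   barcode.
#' @param lambda Poisson mean integrations per cell.
#' @param n_factors Number of factors in the library.
#' @return Capture efficiency in \[0, 1\].
#' @export
#' @examples
#' solve_capture_efficiency(0.91, lambda = 3, n_factors = 88)
solve_capture_efficiency <- function(target_coverage, lambda, n_factors) {
  check_prob(target_coverage, "target_coverage")
  check_pos(lambda, "lambda")
  q <- 1 - exp(-lambda / n_factors)
  e <- (1 - (1 - target_coverage)^(1 / n_factors)) / q
  if (e > 1)
    ms_stop("coverage %.3f unreachable at lambda %.2f with %d factors",
            target_coverage, lambda, n_factors)
  e
}

#' Simulate hybridization capture of integrated barcodes
#'
#' Each true (cell, factor) pair is observed with probability
#' `capture_efficiency`; observed pairs get a UMI count of
#' `1 + rpois(umi_lambda * copies)` so support is always >= 1.
#'
#' @param integrations A `factor_integrations` object (the true assignment).
#' @param capture_efficiency Probability in \[0, 1\] of observing a present
#'   barcode.
#' @param seed Integer seed.
#' @param umi_lambda Poisson rate of extra UMIs per integrated copy.
#' @return data.frame with columns `cell`, `factor`, `umi` (captured pairs
#'   only).
#' @export
simulate_capture <- function(integrations, capture_efficiency, seed = 1L,
                             umi_lambda = 1) {
  stopifnot(inherits(integrations, "factor_integrations"))
  check_prob(capture_efficiency, "capture_efficiency")
  truth <- true_assignment(integrations)
  withr::with_seed(as.integer(seed) + OP_OFFSET[["capture"]], {
    keep <- runif(nrow(truth)) < capture_efficiency
    obs <- truth[keep, , drop = FALSE]
    umi <- 1L + rpois(nrow(obs), umi_lambda * obs$copies)
    data.frame(cell = obs$cell, factor = obs$factor, umi = umi,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

BARCODE_FLANK5 <- "TGCTGGAGTTCGTGACCGCC"  # 20 nt constant 5' flank
BARCODE_FLANK3 <- "GATCACTCTCGGCATGGACG"  # 20 nt constant 3' flank

#' Write captured barcodes as FASTQ reads
#'
#' Emits one read per UMI with layout `flank5 | barcode | flank3` and
#' constant quality "I".
#'
#' @param capture data.frame from [simulate_capture()] (columns `cell`,
#'   `factor`, `umi`).
#' @param whitelist A [make_whitelist()] table mapping barcodes to factors.
#' @param path Output FASTQ path.
#' @param flank5,flank3 Constant flanking sequences.
#' @return `path`, invisibly.
#' @export
write_barcode_fastq <- function(capture, whitelist, path,
                                flank5 = BARCODE_FLANK5,
                                flank3 = BARCODE_FLANK3) {
  bc <- setNames(whitelist$barcode, whitelist$factor)
  missing <- setdiff(unique(capture$factor), names(bc))
  if (length(missing))
    ms_stop("factors absent from whitelist: %s", paste(missing, collapse = ", "))
  idx <- rep(seq_len(nrow(capture)), capture$umi)
  seqs <- paste0(flank5, bc[capture$factor[idx]], flank3)
  ids <- sprintf("@%s_%s_%d", capture$cell[idx], capture$factor[idx],
                 sequence(capture$umi))
  qual <- strrep("I", nchar(seqs[1]))
  writeLines(as.vector(rbind(ids, seqs, "+", qual)), path)
  invisible(path)
}

#' Simulate a sorted/unsorted bulk barcode screen
#'
#' Simulates factor integrations, sorts reporter-positive (meiotic) cells at
#' the configured purity, and tallies per-factor integration copies in the
#' sorted and unsorted populations — the readout of a pooled enrichment
#' screen.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of independent replicate populations.
#' @return A [barcode_count_table()] with one sorted and one unsorted sample
#'   per replicate.
#' @export
simulate_bulk_screen <- function(config, n_replicates = 1L) {
  stopifnot(inherits(config, "sim_config"))
  tabs <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + (r - 1L) * 1000L
    fi <- simulate_factor_integrations(cfg)
    pos <- which(fi$meiotic)
    neg <- which(!fi$meiotic)
    sorted_cells <- with_op_seed(cfg$seed, "sort", {
      if (!length(pos)) integer(0)
      else {
        truly <- runif(length(pos)) < config$sort_purity
        contam <- if (length(neg) && any(!truly))
          sample(neg, sum(!truly), replace = TRUE) else integer(0)
        c(pos[truly], contam)
      }
    })
    rbind(sorted = Matrix::colSums(fi$copies[sorted_cells, , drop = FALSE]),
          unsorted = Matrix::colSums(fi$copies))
  })
  counts <- do.call(rbind, tabs)
  rownames(counts) <- paste0(rep(c("sorted", "unsorted"), n_replicates),
                             "_rep", rep(seq_len(n_replicates), each = 2))
  roles <- setNames(rep(c("sorted", "unsorted"), n_replicates),
                    rownames(counts))
  barcode_count_table(counts, roles)
}
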