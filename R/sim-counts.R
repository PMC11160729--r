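#' Simulate a cell x gene UMI count matrix with known ground truth
#'
#' Draws negative-binomial UMI counts for `config$n_cells` cells in four
#' differentiation states. Gene base means are log-normal; panel genes have
#' their log-mean raised by `panel_mean_shift` in meiotic cells, and each
#' state additionally raises its own disjoint block of `n_state_markers`
#' marker genes by the same shift, so states are mutually distinguishable.
#'
#' @param config A [sim_config()].
#' @param states Optional character vector of per-cell states overriding the
#'   draw from `config$state_proportions` (e.g. states implied by factor
#'   integrations).
#' @return A list with `counts` (sparse `dgCMatrix`, cells x genes, dimnames
#'   set) and `truth` (list with `cell_states`, `panel_genes`,
#'   `state_markers`, `base_log_means`).
#' @export
#' @examples
#' sim <- simulate_count_matrix(sim_config(n_cells = 50, n_genes = 200))
#' dim(sim$counts)
#' table(sim$truth$cell_states)
simulate_count_matrix <- function(config, states = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  g <- config$n_genes
  panel <- config$panel_genes
  m <- config$n_state_markers

  gene_ids <- c(panel,
                unlist(lapply(SIM_STATES, function(s)
                  sprintf("MK_%s_%02d", toupper(s), seq_len(m)))),
                sprintf("G%05d", seq_len(g - length(panel) - 4L * m)))
  cell_ids <- sprintf("cell%06d", seq_len(n))

  if (is.null(states)) {
    states <- with_op_seed(config$seed, "states",
      sample(SIM_STATES, n, replace = TRUE, prob = config$state_proportions))
  } else {
    states <- as.character(states)
    if (length(states) != n || !all(states %in% SIM_STATES))
      ms_stop("invalid `states`: need %d values drawn from {%s}",
              n, paste(SIM_STATES, collapse = ", "))
  }
  names(states) <- cell_ids

  # per-state marker blocks come after the panel block
  marker_idx <- split(length(panel) + seq_len(4L * m),
                      rep(SIM_STATES, each = m))
  counts <- with_op_seed(config$seed, "counts", {
    base_lmu <- rnorm(g, mean = 0, sd = 1)
    names(base_lmu) <- gene_ids
    if (n == 0L) {
      mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, g),
                                  dimnames = list(character(0), gene_ids))
      list(mat = mat, base_lmu = base_lmu)
    } else {
      size <- 1 / config$nb_dispersion
      meiotic <- states %in% MEIOTIC_STATES
      ii <- vector("list", g); jj <- vector("list", g); xx <- vector("list", g)
      for (j in seq_len(g)) {
        lmu <- rep(base_lmu[j], n)
        if (j <= length(panel) && any(meiotic))
          lmu[meiotic] <- lmu[meiotic] + config$panel_mean_shift
        for (s in SIM_STATES) {
          if (j %in% marker_idx[[s]]) {
            in_s <- states == s
            lmu[in_s] <- lmu[in_s] + config$panel_mean_shift
          }
        }
        x <- rnbinom(n, mu = exp(lmu), size = size)
        nz <- which(x > 0L)
        ii[[j]] <- nz; jj[[j]] <- rep.int(j, length(nz)); xx[[j]] <- x[nz]
      }
      mat <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                  x = as.numeric(unlist(xx)),
                                  dims = c(n, g),
                                  dimnames = list(cell_ids, gene_ids))
      list(mat = mat, base_lmu = base_lmu)
    }
  })

  list(counts = counts$mat,
       truth = list(cell_states = states,
                    panel_genes = panel,
                    state_markers = lapply(marker_idx, function(ix) gene_ids[ix]),
                    base_log_means = counts$base_lmu))
}
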