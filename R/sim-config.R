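#' Default meiosis-specific gene panel
#'
#' Nineteen meiosis-specific genes used by default for the per-cell meiosis
#' gene score. Five (REC8, SYCP3, HORMAD1, TEX12, MSH4) are the markers most
#' prominently discussed for staging meiotic entry; the remainder are
#' canonical synaptonemal-complex and meiotic-recombination genes
#' (SYCP1/2, SYCE1/2/3, SIX6OS1, SPO11, DMC1, MEIOB, SPATA22, MND1,
#' PSMC3IP, STAG3, SMC1B) standing in for a lab-specific panel. Override by
#' supplying your own gene list wherever a panel is accepted.
#'
#' @return Character vector of 19 gene symbols.
#' @export
#' @examples
#' default_meiosis_panel()
default_meiosis_panel <- function() {
  c("REC8", "SYCP3", "HORMAD1", "TEX12", "MSH4",
    "SYCP1", "SYCP2", "SYCE1", "SYCE2", "SYCE3", "SIX6OS1",
    "SPO11", "DMC1", "MEIOB", "SPATA22", "MND1", "PSMC3IP",
    "STAG3", "SMC1B")
}

SIM_STATES <- c("pluripotent", "oogonia_like", "meiotic_early", "meiotic_late")
MEIOTIC_STATES <- c("meiotic_early", "meiotic_late")

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*()` generators. Defaults describe a differentiation culture in
#' which most cells are oogonia-like, a small minority has entered meiosis,
#' and a pooled barcoded factor library has been integrated at a few copies
#' per cell.
#'
#' @param n_cells Number of cells to simulate.
#' @param n_genes Number of genes (must be at least
#'   `length(panel_genes) + 4 * n_state_markers`).
#' @param panel_genes Meiosis gene panel; defaults to
#'   [default_meiosis_panel()].
#' @param state_proportions Named fractions over the four states
#'   `pluripotent`, `oogonia_like`, `meiotic_early`, `meiotic_late`;
#'   must sum to 1.
#' @param nb_dispersion Negative-binomial dispersion (inverse size) shared by
#'   all genes.
#' @param panel_mean_shift Log-scale increase of panel-gene means in meiotic
#'   states (and of each state's marker genes in that state).
#' @param n_state_markers Number of marker genes per state, disjoint from the
#'   panel, that identify each of the four states.
#' @param factor_effects Named numeric vector: logit-scale effect of each
#'   library factor on meiotic entry.
#' @param meiotic_baseline Logit-scale intercept of the meiotic-entry model.
#' @param barcode_copy_lambda Poisson mean number of integrations per cell.
#' @param capture_efficiency Probability a present barcode is captured.
#' @param sort_purity Probability a sorted cell is truly reporter-positive.
#' @param seed Integer seed; every generator derives its own stream from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 100, n_genes = 200, seed = 1)
#' cfg$state_proportions
sim_config <- function(n_cells = 1000,
                       n_genes = 2000,
                       panel_genes = default_meiosis_panel(),
                       state_proportions = c(pluripotent = 0.38,
                                             oogonia_like = 0.60,
                                             meiotic_early = 0.015,
                                             meiotic_late = 0.005),
                       nb_dispersion = 0.1,
                       panel_mean_shift = 2,
                       n_state_markers = 30,
                       factor_effects = c(BCL2 = 1.5, HOXB5 = 1, BOLL = 1,
                                          MEIOC = 0.8, STRA8 = 0),
                       meiotic_baseline = qlogis(0.01),
                       barcode_copy_lambda = 3,
                       capture_efficiency = 0.8,
                       sort_purity = 0.95,
                       seed = 1L) {
  check_count(n_cells, "n_cells")
  check_count(n_genes, "n_genes")
  if (length(panel_genes) == 0L || anyDuplicated(panel_genes))
    ms_stop("invalid `panel_genes`: must be non-empty with no duplicates")
  if (!is.numeric(state_proportions) ||
      !setequal(names(state_proportions), SIM_STATES))
    ms_stop("invalid `state_proportions`: must be named over {%s}",
            paste(SIM_STATES, collapse = ", "))
  state_proportions <- state_proportions[SIM_STATES]
  if (any(state_proportions < 0) || any(state_proportions > 1))
    ms_stop("invalid `state_proportions`: fractions must lie in [0, 1]")
  if (abs(sum(state_proportions) - 1) > 1e-9)
    ms_stop("invalid `state_proportions`: must sum to 1 (got %.12f)",
            sum(state_proportions))
  check_pos(nb_dispersion, "nb_dispersion")
  if (!is.numeric(panel_mean_shift) || panel_mean_shift < 0)
    ms_stop("invalid `panel_mean_shift`: must be non-negative")
  check_count(n_state_markers, "n_state_markers")
  if (n_genes < length(panel_genes) + 4L * n_state_markers)
    ms_stop(paste0("invalid `n_genes`: need at least ",
                   "length(panel_genes) + 4 * n_state_markers = %d genes"),
            length(panel_genes) + 4L * n_state_markers)
  if (length(factor_effects) &&
      (is.null(names(factor_effects)) || anyDuplicated(names(factor_effects))))
    ms_stop("invalid `factor_effects`: must be uniquely named")
  check_pos(barcode_copy_lambda, "barcode_copy_lambda")
  check_prob(capture_efficiency, "capture_efficiency")
  check_prob(sort_purity, "sort_purity")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    ms_stop("invalid `seed`: must be a single integer")

  structure(list(
    n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes),
    panel_genes = as.character(panel_genes),
    state_proportions = state_proportions,
    nb_dispersion = nb_dispersion,
    panel_mean_shift = panel_mean_shift,
    n_state_markers = as.integer(n_state_markers),
    factor_effects = factor_effects,
    meiotic_baseline = meiotic_baseline,
    barcode_copy_lambda = barcode_copy_lambda,
    capture_efficiency = capture_efficiency,
    sort_purity = sort_purity,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells x", x$n_genes, "genes,",
      length(x$panel_genes), "panel genes,",
      length(x$factor_effects), "factors, seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$state_proportions <- unlist(raw$state_proportions)
  raw$factor_effects <- unlist(raw$factor_effects)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}
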