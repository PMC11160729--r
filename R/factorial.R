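# --- two-level (fractional) factorial designs and logit-scale effect fits ---

# Resolution of a regular fraction: minimum word length over all non-empty
# products of the generator words. Words are index sets over the full factor
# list (base factors 1..k, generated factors k+1..k+p).
design_resolution <- function(words) {
  if (!length(words)) return(Inf)
  lens <- integer(0)
  for (r in seq_along(words)) {
    cmb <- combn(length(words), r)
    for (j in seq_len(ncol(cmb))) {
      prod <- integer(0)
      for (w in words[cmb[, j]])
        prod <- union(setdiff(prod, w), setdiff(w, prod))  # symmetric diff
      lens <- c(lens, length(prod))
    }
  }
  min(lens)
}

# Built-in maximal-resolution generators for the fractions used here;
# entries are lists of base-factor index vectors, one per generated factor.
default_generators <- function(k, p) {
  key <- paste(k + p, p, sep = ".")
  builtin <- list(
    "7.2" = list(c(1, 2, 3, 4), c(1, 2, 4, 5)),   # 2^(7-2), resolution IV
    "7.3" = list(c(1, 2, 3), c(2, 3, 4), c(1, 3, 4))  # 2^(7-3), resolution IV
  )
  if (!is.null(builtin[[key]])) return(builtin[[key]])
  if (p == 1L) return(list(seq_len(k)))  # product of all base factors
  # exhaustive search over generator-word combinations, maximizing resolution
  cand <- unlist(lapply(2:k, function(sz) combn(k, sz, simplify = FALSE)),
                 recursive = FALSE)
  if (choose(length(cand), p) > 2e4)
    ms_stop("no built-in generators for a 2^(%d-%d) fraction; %s",
            k + p, p, "supply `generators` explicitly")
  combos <- combn(length(cand), p, simplify = FALSE)
  best <- NULL; best_res <- -Inf
  for (cb in combos) {
    words <- lapply(seq_along(cb), function(i) c(cand[[cb[i]]], k + i))
    r <- design_resolution(words)
    if (r > best_res) { best_res <- r; best <- cand[cb] }
  }
  best
}

#' Construct a two-level (fractional) factorial design
#'
#' Builds a regular `2^(n_factors - fraction_exponent)` design: the first
#' `n_factors - fraction_exponent` factors form a full factorial and each
#' remaining factor column is the product of a set of base columns (the
#' defining generators). Built-in generators of resolution IV are provided
#' for the 32-run screen of 7 factors and the 16-run screen of 7 factors;
#' a half fraction uses the product of all base factors; other fractions are
#' found by exhaustive search when feasible.
#'
#' @param n_factors Number of factors.
#' @param fraction_exponent `p` in `2^(k-p)`; 0 gives the full factorial.
#' @param generators Optional list of integer vectors (indices into the base
#'   factors), one per generated factor.
#' @param factor_names Optional factor names (default `LETTERS`).
#' @return A `factorial_design`: list with `factors`, `runs` (run x factor
#'   matrix of -1/+1), and `generators` (human-readable defining relations).
#' @export
#' @examples
#' d <- make_design(7, 2)
#' nrow(d$runs)      # 32
#' d$generators
make_design <- function(n_factors, fraction_exponent = 0L,
                        generators = NULL, factor_names = NULL) {
  check_count(n_factors, "n_factors")
  check_count(fraction_exponent, "fraction_exponent")
  if (n_factors < 1L)
    ms_stop("invalid `n_factors`: must be >= 1")
  if (fraction_exponent >= n_factors)
    ms_stop("invalid `fraction_exponent`: must satisfy 0 <= p < n_factors")
  k <- n_factors - fraction_exponent
  p <- fraction_exponent
  if (is.null(factor_names))
    factor_names <- if (n_factors <= 26) LETTERS[seq_len(n_factors)]
      else sprintf("F%02d", seq_len(n_factors))
  if (length(factor_names) != n_factors || anyDuplicated(factor_names))
    ms_stop("invalid `factor_names`: need %d unique names", n_factors)

  base <- as.matrix(rev(expand.grid(rev(replicate(k, c(-1, 1),
                                                  simplify = FALSE)))))
  colnames(base) <- factor_names[seq_len(k)]
  runs <- base
  if (p > 0L) {
    if (is.null(generators)) generators <- default_generators(k, p)
    if (length(generators) != p)
      ms_stop("need exactly %d generator(s) for a 2^(%d-%d) fraction",
              p, n_factors, p)
    for (i in seq_len(p)) {
      g <- as.integer(generators[[i]])
      if (any(g < 1L) || any(g > k) || anyDuplicated(g))
        ms_stop("generator %d references invalid base-factor indices", i)
      newcol <- apply(base[, g, drop = FALSE], 1, prod)
      # a generated column equal (up to sign) to an existing one aliases a
      # main effect with another main effect
      if (any(apply(runs, 2, function(cc)
        all(cc == newcol) || all(cc == -newcol))))
        ms_stop("aliased_design: generator %d aliases a main effect", i)
      runs <- cbind(runs, newcol)
      colnames(runs)[k + i] <- factor_names[k + i]
    }
  }
  if (anyDuplicated(as.data.frame(runs)))
    ms_stop("aliased_design: duplicate runs in design")
  rownames(runs) <- sprintf("run%02d", seq_len(nrow(runs)))
  gen_str <- if (p > 0L)
    vapply(seq_len(p), function(i)
      paste(factor_names[k + i], "=",
            paste(factor_names[generators[[i]]], collapse = "*")),
      character(1))
    else character(0)
  structure(list(factors = factor_names, runs = runs, generators = gen_str),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("factorial_design: %d runs x %d factors (%s)\n",
              nrow(x$runs), length(x$factors),
              if (length(x$generators))
                paste(x$generators, collapse = "; ") else "full factorial"))
  invisible(x)
}

#' Logit transform with boundary clipping
#'
#' Fractions are clipped to `[epsilon, 1 - epsilon]` before taking
#' `log(p / (1 - p))`, keeping wells at 0 or 1 finite.
#'
#' @param fractions Numeric vector of fractions in \[0, 1\].
#' @param epsilon Clipping bound in (0, 0.5).
#' @return Numeric vector of logits.
#' @export
#' @examples
#' logit_transform(c(0, 0.5, 0.9), epsilon = 0.005)
logit_transform <- function(fractions, epsilon = 0.005) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    ms_stop("invalid `epsilon`: must lie in (0, 0.5)")
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    ms_stop("fractions must lie in [0, 1]")
  p <- pmin(pmax(fractions, epsilon), 1 - epsilon)
  qlogis(p)
}

#' Simulate reporter-positive fractions for a factorial screen
#'
#' Well response is `plogis(intercept + runs %*% effects / 2 + block effect
#' + Gaussian noise on the logit scale)`, replicated once per block (cell
#' line). With this parameterization a factor's true effect equals the
#' difference in mean logit response between its +1 and -1 runs.
#'
#' @param design A [make_design()] object.
#' @param true_effects Named numeric vector of logit-scale effects matching
#'   `design$factors`.
#' @param intercept Logit-scale intercept.
#' @param noise_sd SD of Gaussian logit-scale well noise.
#' @param n_reps Number of replicate blocks (cell lines).
#' @param seed Integer seed.
#' @param block_effects Optional numeric vector (length `n_reps`) of additive
#'   logit-scale block effects; default all zero.
#' @return A data.frame (`run`, `block`, `fraction_positive`).
#' @export
simulate_screen_wells <- function(design, true_effects, intercept = 0,
                                  noise_sd = 0.1, n_reps = 2L, seed = 1L,
                                  block_effects = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  if (is.null(names(true_effects)))
    names(true_effects) <- design$factors
  if (!setequal(names(true_effects), design$factors))
    ms_stop("`true_effects` names must match design factors")
  true_effects <- true_effects[design$factors]
  if (noise_sd < 0) ms_stop("invalid `noise_sd`: must be >= 0")
  if (is.null(block_effects)) block_effects <- numeric(n_reps)
  stopifnot(length(block_effects) == n_reps)
  eta0 <- intercept + as.numeric(design$runs %*% true_effects) / 2
  withr::with_seed(as.integer(seed) + OP_OFFSET[["wells"]], {
    do.call(rbind, lapply(seq_len(n_reps), function(b) {
      eta <- eta0 + block_effects[b] +
        if (noise_sd > 0) rnorm(length(eta0), 0, noise_sd) else 0
      data.frame(run = rownames(design$runs),
                 block = sprintf("line%d", b),
                 fraction_positive = plogis(eta),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
}

#' Estimate factorial main effects from logit-transformed fractions
#'
#' Ordinary least squares of logit-transformed well fractions on an
#' intercept, the -1/+1 factor columns, and additive block (cell line)
#' indicators when more than one block is present. Reported effects are
#' twice the coefficient of the coded column, i.e. the difference in mean
#' logit response between a factor's +1 and -1 runs; two-sided p-values use
#' the t distribution on the residual degrees of freedom.
#'
#' @param design A [make_design()] object.
#' @param response data.frame with columns `run`, `block`,
#'   `fraction_positive`, optionally `n_cells`.
#' @param epsilon Logit clipping bound; default `1 / (2 * n_cells)` per well
#'   when cell counts are provided, else 0.005.
#' @return An `effect_estimates`: list with `effects` (data.frame `factor`,
#'   `effect`, `se`, `t`, `p`), `intercept`, `block_effects`, `residual_df`,
#'   `epsilon`.
#' @export
#' @examples
#' d <- make_design(3, 0)
#' resp <- simulate_screen_wells(d, c(A = 1, B = 0, C = -0.5), noise_sd = 0)
#' fit_main_effects(d, resp)$effects
fit_main_effects <- function(design, response, epsilon = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  need <- c("run", "block", "fraction_positive")
  if (!all(need %in% names(response)))
    ms_stop("response needs columns %s", paste(need, collapse = ", "))
  miss <- setdiff(rownames(design$runs), response$run)
  if (length(miss))
    ms_stop("design runs without responses: %s",
            paste(head(miss, 3), collapse = ", "))
  bad <- setdiff(response$run, rownames(design$runs))
  if (length(bad))
    ms_stop("responses for unknown runs: %s",
            paste(head(bad, 3), collapse = ", "))

  if (is.null(epsilon)) {
    eps <- if ("n_cells" %in% names(response) &&
               all(is.finite(response$n_cells)) && all(response$n_cells > 0))
      1 / (2 * response$n_cells) else rep(0.005, nrow(response))
  } else eps <- rep(epsilon, nrow(response))
  y <- vapply(seq_len(nrow(response)), function(i)
    logit_transform(response$fraction_positive[i], eps[i]), numeric(1))

  X <- design$runs[response$run, , drop = FALSE]
  blocks <- factor(response$block)
  n_blk <- nlevels(blocks)
  df_model <- 1L + ncol(X) + (n_blk - 1L)
  if (nrow(response) < df_model)
    ms_stop("insufficient_df: %d rows cannot estimate %d parameters",
            nrow(response), df_model)

  dat <- data.frame(y = y, X, check.names = FALSE)
  fml <- if (n_blk > 1) {
    dat$block <- blocks
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)),
                                         collapse = " + "), "+ block"))
  } else
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)),
                                         collapse = " + ")))
  ct <- list(block = "contr.sum")
  fit <- if (n_blk > 1) lm(fml, data = dat, contrasts = ct)
    else lm(fml, data = dat)
  cf <- suppressWarnings(summary(fit))$coefficients  # silence exact-fit note
  rdf <- fit$df.residual
  fac_rows <- match(sprintf("`%s`", colnames(X)), rownames(cf))
  fac_rows[is.na(fac_rows)] <- match(colnames(X), rownames(cf))[is.na(fac_rows)]
  eff <- data.frame(factor = colnames(X),
                    effect = 2 * cf[fac_rows, "Estimate"],
                    se = if (rdf > 0) 2 * cf[fac_rows, "Std. Error"]
                         else NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  eff$t <- eff$effect / eff$se
  eff$p <- if (rdf > 0) 2 * pt(abs(eff$t), df = rdf, lower.tail = FALSE)
    else NA_real_
  blk <- if (n_blk > 1) {
    bcf <- coef(fit)[grep("^block", names(coef(fit)))]
    setNames(c(bcf, -sum(bcf)), levels(blocks))
  } else setNames(numeric(0), character(0))
  structure(list(effects = eff,
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 block_effects = blk,
                 residual_df = rdf,
                 se_available = rdf > 0,
                 epsilon = eps),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("effect_estimates (logit scale), residual df = %d%s\n",
              x$residual_df,
              if (!x$se_available) "; SE/p unavailable (zero df)" else ""))
  print(x$effects, digits = 4)
  invisible(x)
}
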