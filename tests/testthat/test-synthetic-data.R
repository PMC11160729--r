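test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_cells = -1), "n_cells")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(capture_efficiency = 1.2), "capture_efficiency")
  expect_error(sim_config(barcode_copy_lambda = -2), "barcode_copy_lambda")
  expect_error(
    sim_config(state_proportions = c(pluripotent = 0.5, oogonia_like = 0.6,
                                     meiotic_early = 0, meiotic_late = 0)),
    "state_proportions")
  expect_error(sim_config(panel_genes = c("A", "A")), "panel_genes")
})

test_that("generators are deterministic given config and seed", {
  cfg <- tiny_config(seed = 99L)
  expect_identical(simulate_count_matrix(cfg), simulate_count_matrix(cfg))
  expect_identical(simulate_factor_integrations(cfg),
                   simulate_factor_integrations(cfg))
  fi <- simulate_factor_integrations(cfg)
  expect_identical(simulate_capture(fi, 0.5, seed = 3),
                   simulate_capture(fi, 0.5, seed = 3))
  expect_identical(simulate_timecourse(seed = 5), simulate_timecourse(seed = 5))
  # a different seed actually changes the draw
  cfg2 <- tiny_config(seed = 100L)
  expect_false(identical(simulate_count_matrix(cfg)$counts,
                         simulate_count_matrix(cfg2)$counts))
})

test_that("zero cells give an empty matrix and empty ground truth", {
  sim <- simulate_count_matrix(tiny_config(n_cells = 0L))
  expect_equal(dim(sim$counts), c(0L, 120L))
  expect_length(sim$truth$cell_states, 0)
})

test_that("count matrices are non-negative integers with unique labels", {
  sim <- simulate_count_matrix(tiny_config(n_cells = 200L))
  x <- sim$counts@x
  expect_true(all(x >= 0) && all(x == floor(x)))
  expect_false(anyDuplicated(rownames(sim$counts)) > 0)
  expect_false(anyDuplicated(colnames(sim$counts)) > 0)
  expect_true(all(names(sim$truth$cell_states) == rownames(sim$counts)))
})

test_that("a zero panel shift leaves panel genes equal across states", {
  cfg <- sim_config(n_cells = 5000L, n_genes = 120L, n_state_markers = 10L,
                    panel_mean_shift = 0,
                    state_proportions = c(pluripotent = 0.25,
                                          oogonia_like = 0.25,
                                          meiotic_early = 0.25,
                                          meiotic_late = 0.25),
                    seed = 7L)
  sim <- simulate_count_matrix(cfg)
  meiotic <- sim$truth$cell_states %in% c("meiotic_early", "meiotic_late")
  for (g in cfg$panel_genes) {
    a <- as.numeric(sim$counts[meiotic, g])
    b <- as.numeric(sim$counts[!meiotic, g])
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-12)
  }
})

test_that("rare meiotic proportions are recovered at scale", {
  # 0.8% meiotic overall, the abundance seen in sorted SYCP3+ samples
  cfg <- sim_config(n_cells = 50000L, n_genes = 19L, n_state_markers = 0L,
                    state_proportions = c(pluripotent = 0.2,
                                          oogonia_like = 0.792,
                                          meiotic_early = 0.004,
                                          meiotic_late = 0.004),
                    seed = 3L)
  sim <- simulate_count_matrix(cfg)
  frac <- mean(sim$truth$cell_states %in% c("meiotic_early", "meiotic_late"))
  half <- qnorm(0.995) * sqrt(0.008 * 0.992 / 50000)
  expect_lt(abs(frac - 0.008), half)
})

test_that("integrations follow the Poisson copy model", {
  # vanishing lambda: essentially no cell carries an integration
  cfg <- tiny_config(n_cells = 10000L, barcode_copy_lambda = 1e-9)
  fi <- simulate_factor_integrations(cfg)
  expect_gte(mean(Matrix::rowSums(fi$copies) == 0), 0.999)

  # all effects zero: meiotic fraction matches the inverse-logit baseline
  b <- -1.5
  cfg <- tiny_config(n_cells = 10000L, meiotic_baseline = b,
                     factor_effects = c(F1 = 0, F2 = 0, F3 = 0))
  fi <- simulate_factor_integrations(cfg)
  p <- plogis(b)
  expect_lt(abs(mean(fi$meiotic) - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(
    simulate_factor_integrations(tiny_config(factor_effects = numeric(0))),
    "factor_effects")
})

test_that("an 88-factor pool yields an 88-entry whitelist", {
  wl <- make_whitelist(sprintf("FCT%02d", 1:88), seed = 2)
  expect_equal(nrow(wl), 88L)
  expect_false(anyDuplicated(wl$barcode) > 0)
  dmin <- min(vapply(1:87, function(i)
    min(meioscreen:::hamming(wl$barcode[i], wl$barcode[(i + 1):88])),
    numeric(1)))
  expect_gte(dmin, 3)
})

test_that("capture is the identity at efficiency 1 and empty at 0", {
  cfg <- tiny_config(n_cells = 300L)
  fi <- simulate_factor_integrations(cfg)
  truth <- true_assignment(fi)
  cap1 <- simulate_capture(fi, 1, seed = 4)
  expect_equal(cap1[c("cell", "factor")], truth[c("cell", "factor")],
               ignore_attr = TRUE)
  expect_true(all(cap1$umi >= 1))
  cap0 <- simulate_capture(fi, 0, seed = 4)
  expect_equal(nrow(cap0), 0L)
})

test_that("screen wells follow the logit-linear generator", {
  d <- make_design(3, 0)
  flat <- simulate_screen_wells(d, c(A = 0, B = 0, C = 0), intercept = 0.7,
                                noise_sd = 0, n_reps = 1, seed = 1)
  expect_equal(flat$fraction_positive, rep(plogis(0.7), 8))
  two <- simulate_screen_wells(d, c(A = 1, B = 0, C = 0), n_reps = 2, seed = 1)
  expect_equal(nrow(two), 16L)  # runs x 2 cell lines
  expect_setequal(unique(two$block), c("line1", "line2"))
})

test_that("timecourse counts respect onsets and the growth curve", {
  expect_equal(nrow(simulate_timecourse(n_days = 0L)), 0L)
  tc <- simulate_timecourse(true_onsets = c(zyg = 3), n_days = 8,
                            stage_rate = 50, seed = 2)
  expect_true(all(tc$count[tc$stage == "zyg" & tc$day < 3] == 0))
  expect_equal(detect_onset(tc, "zyg"), 3L)
  # ~8-fold growth: day-7 totals about 8x day-1 totals
  tot <- aggregate(count ~ day, tc, sum)
  ratio <- tot$count[tot$day == 7] / tot$count[tot$day == 1]
  expect_gt(ratio, 5)
  expect_lt(ratio, 11)
})
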