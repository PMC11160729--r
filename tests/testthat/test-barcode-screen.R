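test_that("reads are counted, corrected, or discarded with reasons", {
  wl <- fixed_whitelist()
  reads <- c(make_read("AAAAAAAAAAAA"),              # exact -> BCL2
             make_read("AAAAAAAAAAAT"),              # 1 mismatch -> BCL2
             make_read("AAAAAAAAAATT"),              # 2 mismatches -> no_match
             make_read("CCCCCCCCCCCC", flank5 = strrep("T", 20)))  # bad flank
  tab <- extract_barcodes(reads, wl, max_mismatch = 1)
  expect_equal(unname(tab$counts[1, ]), c(2L, 0L, 0L))
  disc <- attr(tab, "discarded")
  expect_equal(unname(disc["no_match"]), 1L)
  expect_equal(unname(disc["flank_mismatch"]), 1L)

  # with max_mismatch = 0 the 1-mismatch read is discarded too
  tab0 <- extract_barcodes(reads, wl, max_mismatch = 0)
  expect_equal(unname(tab0$counts[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(attr(tab0, "discarded")["no_match"]), 2L)
  expect_error(extract_barcodes(reads, wl, max_mismatch = 2), "max_mismatch")
})

test_that("reads within one mismatch of two entries are discarded as multi hits", {
  wl <- structure(data.frame(barcode = c("AAAAAAAAAAAA", "AAAAAAAAAATT"),
                             factor = c("X", "Y"), stringsAsFactors = FALSE),
                  class = c("barcode_whitelist", "data.frame"))
  tab <- extract_barcodes(make_read("AAAAAAAAAAAT"), wl, max_mismatch = 1)
  expect_equal(sum(tab$counts), 0)
  expect_equal(unname(attr(tab, "discarded")["multi_match"]), 1L)
})

test_that("malformed FASTQ records are reported with a line number", {
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_lines(c(make_read("AAAAAAAAAAAA"), make_read("CCCCCCCCCCCC")),
                    path,
                    mangle = function(l) { l[7] <- "oops"; l })
  expect_error(extract_barcodes(path, fixed_whitelist()), "line 7")
  write_fastq_lines(make_read("AAAAAAAAAAAA"), path,
                    mangle = function(l) l[1:3])
  expect_error(extract_barcodes(path, fixed_whitelist()), "multiple of 4")
})

test_that("simulated capture FASTQ round-trips through barcode extraction", {
  cfg <- tiny_config(n_cells = 150L, seed = 8L)
  fi <- simulate_factor_integrations(cfg)
  cap <- simulate_capture(fi, 0.9, seed = 8)
  wl <- make_whitelist(fi$factors, seed = 8)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_barcode_fastq(cap, wl, path)
  tab <- extract_barcodes(path, wl)
  per_factor <- tapply(cap$umi, factor(cap$factor, levels = wl$factor), sum,
                       default = 0L)
  expect_equal(unname(tab$counts[1, wl$factor]), unname(as.integer(per_factor)))
  expect_equal(sum(attr(tab, "discarded")), 0L)
})

test_that("enrichment matches hand-computed frequency ratios", {
  tab <- barcode_count_table(
    matrix(c(30, 10, 10, 30), 2, byrow = TRUE,
           dimnames = list(c("s1", "u1"), c("A", "B"))),
    c(s1 = "sorted", u1 = "unsorted"))
  res <- enrich(tab, pseudocount = 0)
  expect_equal(res$summary$mean_log2_enrichment,
               c(log2(3), -log2(3)), tolerance = 1e-12)
  # identical counts: enrichment exactly zero
  same <- barcode_count_table(
    matrix(c(5, 7, 5, 7), 2, byrow = TRUE,
           dimnames = list(c("s1", "u1"), c("A", "B"))),
    c(s1 = "sorted", u1 = "unsorted"))
  expect_equal(enrich(same, 0)$summary$mean_log2_enrichment, c(0, 0))
  # zero sorted count stays finite with a pseudocount
  zero <- barcode_count_table(
    matrix(c(0, 40, 10, 30), 2, byrow = TRUE,
           dimnames = list(c("s1", "u1"), c("A", "B"))),
    c(s1 = "sorted", u1 = "unsorted"))
  l2 <- enrich(zero, 0.5)$summary$mean_log2_enrichment
  expect_true(all(is.finite(l2)))
  expect_lt(l2[1], 0)
})

test_that("frequencies normalize and enrichment obeys its symmetries", {
  counts <- matrix(c(12, 3, 25, 8, 30, 2), 2, byrow = TRUE,
                   dimnames = list(c("s1", "u1"), c("A", "B", "C")))
  tab <- barcode_count_table(counts, c(s1 = "sorted", u1 = "unsorted"))
  res <- enrich(tab, 0.5)
  expect_equal(sum(res$per_pair$freq_sorted), 1, tolerance = 1e-9)
  expect_equal(sum(res$per_pair$freq_unsorted), 1, tolerance = 1e-9)
  # scale invariance at pseudocount 0
  scaled <- barcode_count_table(counts * 10L,
                                c(s1 = "sorted", u1 = "unsorted"))
  expect_equal(enrich(scaled, 0)$summary$mean_log2_enrichment,
               enrich(tab, 0)$summary$mean_log2_enrichment)
  # swapping roles negates every enrichment exactly
  swapped <- barcode_count_table(counts, c(s1 = "unsorted", u1 = "sorted"))
  expect_equal(enrich(swapped, 0.5)$summary$mean_log2_enrichment,
               -res$summary$mean_log2_enrichment)
  # a sample with zero totals is rejected
  empty <- barcode_count_table(
    matrix(c(0, 0, 10, 30), 2, byrow = TRUE,
           dimnames = list(c("s1", "u1"), c("A", "B"))),
    c(s1 = "sorted", u1 = "unsorted"))
  expect_error(enrich(empty, 0.5), "empty_sample")
})

test_that("consistency ranking prefers sign agreement over magnitude", {
  mk <- function(l2) structure(
    list(per_pair = data.frame(factor = names(l2), log2_enrichment = l2,
                               stringsAsFactors = FALSE)),
    class = "enrichment_result")
  # A modestly up in all three conditions; B hugely up in two, down in one
  rk <- rank_consistent(list(mk(c(A = 0.5, B = 4, C = -1)),
                             mk(c(A = 0.6, B = 5, C = -1)),
                             mk(c(A = 0.4, B = -0.2, C = -1))))
  expect_equal(rk$factor, c("A", "B", "C"))
  expect_equal(rk$frac_positive, c(1, 2 / 3, 0))
  expect_equal(rk$rank, 1:3)
  # single condition: order equals order by log2 enrichment
  tab <- barcode_count_table(
    matrix(c(30, 5, 20, 10, 20, 25), 2, byrow = TRUE,
           dimnames = list(c("s1", "u1"), c("A", "B", "C"))),
    c(s1 = "sorted", u1 = "unsorted"))
  r1 <- enrich(tab, 0.5)
  rk1 <- rank_consistent(r1)
  expect_equal(rk1$factor,
               r1$summary$factor[order(-r1$summary$mean_log2_enrichment)])
  # all-zero enrichments: alphabetical tie-break
  flat <- mk(c(B = 0, A = 0, C = 0))
  expect_equal(rank_consistent(flat)$factor, c("A", "B", "C"))
})

test_that("a strong factor tops the ranking across seeded bulk screens", {
  eff <- setNames(c(2, rep(0, 9)), c("HIT", sprintf("f%02d", 1:9)))
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cells = 3000L, factor_effects = eff,
                      meiotic_baseline = qlogis(0.02),
                      barcode_copy_lambda = 2, seed = s)
    tab <- simulate_bulk_screen(cfg, n_replicates = 2)
    rank_consistent(enrich(tab))$factor[1] == "HIT"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
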