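# shared fixture builders

tiny_config <- function(...) {
  defaults <- list(n_cells = 60L, n_genes = 120L, n_state_markers = 10L,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# dense count matrix from a vector spec, cells x genes with names
dense_counts <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, genes)
  m
}

# a small whitelist with known, maximally separated barcodes
fixed_whitelist <- function() {
  structure(data.frame(
    barcode = c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG"),
    factor = c("BCL2", "HOXB5", "BOLL"),
    stringsAsFactors = FALSE),
    class = c("barcode_whitelist", "data.frame"))
}

make_read <- function(barcode, flank5 = meioscreen:::BARCODE_FLANK5,
                      flank3 = meioscreen:::BARCODE_FLANK3) {
  paste0(flank5, barcode, flank3)
}

write_fastq_lines <- function(seqs, path, mangle = identity) {
  recs <- unlist(lapply(seq_along(seqs), function(i)
    c(sprintf("@read%d", i), seqs[i], "+", strrep("I", nchar(seqs[i])))))
  writeLines(mangle(recs), path)
  path
}
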