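# Matrix-Market I/O in the 10x-style dialect: matrix.mtx holds the
# genes-in-rows triplets with 1-based indices, features.tsv lists genes,
# barcodes.tsv lists cell barcodes. In memory this package keeps counts as
# cells x genes, so the matrix is transposed on the way through.

#' Write a count matrix as Matrix-Market plus label files
#'
#' Creates `matrix.mtx` (genes x cells triplets), `features.tsv` (genes) and
#' `barcodes.tsv` (cells) in `dir`, optionally gzip-compressed.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param gzip Write `.gz`-compressed files.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  m <- Matrix::t(methods::as(methods::as(counts, "CsparseMatrix"),
                             "generalMatrix"))
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  if (gzip) {
    gzip_file(mtx)
  }
  wl <- function(x, f) {
    con <- if (gzip) gzfile(file.path(dir, paste0(f, ext))) else
      file.path(dir, f)
    writeLines(x, con)
    if (gzip) close(con)
  }
  wl(colnames(counts), "features.tsv")
  wl(rownames(counts), "barcodes.tsv")
  invisible(dir)
}

# gzip a file in place without extra dependencies
gzip_file <- function(path) {
  con_in <- file(path, "rb")
  raw <- readBin(con_in, "raw", file.size(path))
  close(con_in)
  con_out <- gzfile(paste0(path, ".gz"), "wb")
  writeBin(raw, con_out)
  close(con_out)
  unlink(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Accepts plain or gzip-compressed `matrix.mtx` / `features.tsv` /
#' `barcodes.tsv`.
#'
#' @param dir Directory containing the three files.
#' @return Sparse cells x genes `dgCMatrix` with dimnames.
#' @export
read_count_matrix <- function(dir) {
  pick <- function(f) {
    for (p in file.path(dir, c(f, paste0(f, ".gz"))))
      if (file.exists(p)) return(p)
    ms_stop("missing %s in %s", f, dir)
  }
  m <- Matrix::readMM(pick("matrix.mtx"))
  genes <- readLines(pick("features.tsv"))
  cells <- readLines(pick("barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    ms_stop("matrix dimensions (%d x %d) do not match label files (%d genes, %d cells)",
            nrow(m), ncol(m), length(genes), length(cells))
  out <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(out) <- list(cells, genes)
  out
}

#' Read bulk barcode counts from CSV
#'
#' Expected columns: `sample`, `role`, then one column per factor.
#'
#' @param path CSV path.
#' @return A [barcode_count_table()].
#' @export
read_barcode_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "role") %in% names(df)))
    ms_stop("counts CSV needs columns 'sample' and 'role'")
  counts <- as.matrix(df[, setdiff(names(df), c("sample", "role")),
                         drop = FALSE])
  rownames(counts) <- df$sample
  barcode_count_table(counts, setNames(df$role, df$sample))
}

#' @rdname read_barcode_counts
#' @param table A [barcode_count_table()].
#' @export
write_barcode_counts <- function(table, path) {
  df <- data.frame(sample = rownames(table$counts),
                   role = unname(table$roles),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene panel file (one gene per line)
#'
#' @param path Text file path.
#' @return Character vector of gene identifiers.
#' @export
read_panel <- function(path) {
  genes <- trimws(readLines(path))
  genes[nzchar(genes)]
}
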