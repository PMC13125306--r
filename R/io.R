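#' Write a cohort as a 10x-style MTX triple plus side tables
#'
#' Emits `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv`,
#' `barcodes.tsv`, `gene_positions.tsv` (gene, chrom, start, end, cytoband;
#' 1-based inclusive) and `annotations.tsv` (cell metadata).
#'
#' @param x a `cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(x$counts), sparse = TRUE)  # genes x cells, 10x layout
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(x$genes, file.path(dir, "gene_positions.tsv"))
  write_tsv(x$cells, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Read a cohort from a 10x-style directory
#'
#' Expects the layout produced by [write_10x()]: an MTX triple plus
#' `gene_positions.tsv` and `annotations.tsv`.
#'
#' @param dir directory path.
#' @return a `cohort`.
#' @export
read_10x <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feats, bcs)
  genes <- read_tsv(file.path(dir, "gene_positions.tsv"))
  cells <- read_tsv(file.path(dir, "annotations.tsv"))
  cells$is_reference <- as.logical(cells$is_reference)
  cells$histology[cells$histology %in% c("NA", "")] <- NA
  new_cohort(t(m), cells, genes)
}

#' Read a dense count TSV (cells in rows, genes in columns)
#'
#' @param path TSV with a `cell` id column followed by one column per gene.
#' @param genes gene-position data.frame; `cells` optional metadata (defaults
#'   to single-sample, non-reference, unknown histology).
#' @param cells optional cell metadata data.frame.
#' @return a `cohort`.
#' @export
read_dense_counts <- function(path, genes, cells = NULL) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (is.null(cells)) {
    cells <- data.frame(cell = rownames(m), sample = "sample1",
                        histology = NA_character_, is_reference = FALSE)
  }
  new_cohort(m, cells, genes)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
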