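#' Cohort container: counts + cell metadata + gene positions
#'
#' A `cohort` bundles a raw count matrix (cells in rows, genes in columns),
#' per-cell metadata and the gene-position table that defines genome order.
#' It is the common currency of the whole pipeline: the simulator emits one,
#' QC filters one, CNV inference consumes one.
#'
#' @param counts integer matrix, cells x genes, with unique row (cell) and
#'   column (gene) names.
#' @param cells data.frame with one row per cell: columns `cell`, `sample`,
#'   `histology` (one of `"DCIS"`, `"IDC"`, `"normal"` or `NA`),
#'   `is_reference` (logical), and optionally spatial `x`/`y`.
#' @param genes data.frame with one row per gene: columns `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive), `cytoband`.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(counts, cells, genes) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique cell (row) names")
  assert_that(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
              "counts must have unique gene (column) names")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  assert_that(all(c("cell", "sample", "histology", "is_reference") %in% names(cells)),
              "cells needs columns cell, sample, histology, is_reference")
  assert_that(all(rownames(counts) == cells$cell),
              "cells table must align with count matrix rows")
  assert_that(all(c("gene", "chrom", "start", "end") %in% names(genes)),
              "genes needs columns gene, chrom, start, end")
  assert_that(all(colnames(counts) == genes$gene),
              "gene table must align with count matrix columns")
  assert_that(all(genes$end >= genes$start), "zero/negative-length gene in positions")
  bad <- cells$histology[!is.na(cells$histology)]
  assert_that(all(bad %in% c("DCIS", "IDC", "normal")),
              "histology must be DCIS, IDC, normal or NA")
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells x %d genes, %d sample(s), %d reference cell(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample)), sum(x$cells$is_reference)))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$counts)

#' Subset a cohort by cell and/or gene identifiers
#'
#' @param x a `cohort`.
#' @param cells,genes character vectors of ids to keep (default: all).
#' @return a `cohort`.
#' @export
subset_cohort <- function(x, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) rownames(x$counts) else cells
  gi <- if (is.null(genes)) colnames(x$counts) else genes
  new_cohort(x$counts[ci, gi, drop = FALSE],
             x$cells[match(ci, x$cells$cell), , drop = FALSE],
             x$genes[match(gi, x$genes$gene), , drop = FALSE])
}

## Genome order: chromosomes in first-appearance order of the gene table,
## genes by start position within chromosome.
genome_order <- function(genes) {
  chrom <- factor(genes$chrom, levels = unique(genes$chrom))
  order(as.integer(chrom), genes$start)
}

#' Identify mitochondrial genes
#'
#' Mitochondrial genes are recognised by gene-name prefix (default `"MT-"`)
#' or by chromosome `"chrM"`/`"MT"`; both routes are checked because public
#' matrices annotate them inconsistently.
#'
#' @param genes gene-position data.frame (columns `gene`, `chrom`).
#' @param prefix gene-name prefix marking mitochondrial transcripts.
#' @return logical vector over genes.
#' @export
is_mito_gene <- function(genes, prefix = "MT-") {
  startsWith(genes$gene, prefix) | genes$chrom %in% c("chrM", "MT")
}
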