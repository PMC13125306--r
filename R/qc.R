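## ---------------------------------------------------------------------------
## Quality control, normalization, feature selection, clustering, annotation.
## ---------------------------------------------------------------------------

#' QC thresholds
#'
#' Defaults are the standard droplet-QC rule set: cells are dropped when they
#' have fewer than 200 UMIs, fewer than 200 or more than 6,000 detected genes,
#' or more than 20% mitochondrial UMIs.
#'
#' @param min_umis,min_genes,max_genes,max_mito_fraction thresholds.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umis = 200L, min_genes = 200L,
                          max_genes = 6000L, max_mito_fraction = 0.20) {
  assert_that(min_genes < max_genes, "min_genes must be < max_genes")
  assert_that(max_mito_fraction > 0 && max_mito_fraction <= 1,
              "max_mito_fraction must be in (0, 1]")
  structure(list(min_umis = min_umis, min_genes = min_genes,
                 max_genes = max_genes, max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' A cell is retained iff UMIs >= `min_umis`, `min_genes` <= detected genes
#' <= `max_genes`, and mitochondrial fraction <= `max_mito_fraction`.
#' Mitochondrial genes are found via [is_mito_gene()].
#'
#' @param x a `cohort`.
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return list with `cohort` (retained cells) and `report` (per-criterion
#'   violation counts; a cell can violate several criteria at once).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds(), mito_prefix = "MT-") {
  umis <- rowSums(x$counts)
  ngenes <- rowSums(x$counts > 0)
  mito <- is_mito_gene(x$genes, mito_prefix)
  mfrac <- if (any(mito)) rowSums(x$counts[, mito, drop = FALSE]) / pmax(umis, 1)
           else rep(0, nrow(x$counts))
  v_umis <- umis < thresholds$min_umis
  v_low <- ngenes < thresholds$min_genes
  v_high <- ngenes > thresholds$max_genes
  v_mito <- mfrac > thresholds$max_mito_fraction
  keep <- !(v_umis | v_low | v_high | v_mito)
  if (!any(keep)) stopf("QC removed every cell (%d input cells)", length(keep))
  report <- data.frame(
    criterion = c("low_umis", "low_genes", "high_genes", "high_mito"),
    threshold = c(thresholds$min_umis, thresholds$min_genes,
                  thresholds$max_genes, thresholds$max_mito_fraction),
    n_violating = c(sum(v_umis), sum(v_low), sum(v_high), sum(v_mito)))
  attr(report, "n_input") <- length(keep)
  attr(report, "n_retained") <- sum(keep)
  list(cohort = subset_cohort(x, cells = rownames(x$counts)[keep]),
       report = report)
}

#' Library-size normalization followed by log1p
#'
#' Each cell is scaled to `scale` total counts, then `log(1 + x)` is applied.
#' All-zero cells map to all-zero rows.
#'
#' @param x a `cohort` or a raw count matrix (cells x genes).
#' @param scale target total per cell.
#' @return numeric matrix, cells x genes.
#' @export
normalize_log1p <- function(x, scale = 1e4) {
  m <- if (inherits(x, "cohort")) x$counts else as.matrix(x)
  assert_that(nrow(m) > 0 && ncol(m) > 0, "empty matrix")
  tot <- rowSums(m)
  fac <- ifelse(tot > 0, scale / tot, 0)
  log1p(m * fac)
}

#' Select highly variable genes by a vst-style mean-variance trend
#'
#' Fits a second-degree polynomial to log10(variance) vs log10(mean) over
#' genes with positive variance, standardizes each gene by its trend-predicted
#' SD with values clipped at sqrt(N), and ranks genes by the variance of the
#' clipped standardized values.
#'
#' @param e expression or count matrix, cells x genes.
#' @param n number of genes to return.
#' @return character vector of the `n` top-ranked gene names.
#' @export
select_hvg_vst <- function(e, n = 2000L) {
  assert_that(n <= ncol(e), "n exceeds the number of genes")
  mu <- colMeans(e)
  v <- apply(e, 2, stats::var)
  ok <- v > 0 & mu > 0
  if (sum(ok) < 10) stopf("fewer than 10 genes with nonzero variance")
  fit <- stats::lm(log10(v[ok]) ~ stats::poly(log10(mu[ok]), 2))
  sd_pred <- rep(NA_real_, length(v))
  sd_pred[ok] <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(nrow(e))
  std_var <- rep(0, length(v))
  for (j in which(ok)) {
    z <- pmin((e[, j] - mu[j]) / sd_pred[j], clip)
    std_var[j] <- stats::var(z)
  }
  names(std_var) <- colnames(e)
  names(sort(std_var, decreasing = TRUE))[seq_len(n)]
}

## Euclidean kNN indices (n x k), excluding self; brute force on PCs.
knn_index <- function(pcs, k) {
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' PCA, SNN graph and modularity clustering
#'
#' Scales genes, runs PCA, optionally centres principal-component coordinates
#' per batch (the package's lightweight stand-in for dedicated batch
#' integration), builds a Jaccard-weighted shared-nearest-neighbor graph and
#' clusters it by modularity optimization (Louvain) at the given resolution.
#'
#' @param e expression matrix, cells x genes (typically HVG-restricted).
#' @param n_pcs number of principal components.
#' @param resolution modularity resolution parameter.
#' @param k neighbors for the kNN/SNN graph.
#' @param seed RNG seed (community detection is seeded).
#' @param batch optional per-cell batch labels for PC centering.
#' @param prune SNN edges with Jaccard weight below this are dropped.
#' @return integer cluster labels (named by cell).
#' @export
cluster_snn <- function(e, n_pcs = 30L, resolution = 0.1, k = 20L,
                        seed = 1L, batch = NULL, prune = 1 / 15) {
  assert_that(n_pcs <= min(dim(e)), "n_pcs exceeds min(cells, genes)")
  es <- scale(e)
  es[, attr(es, "scaled:scale") == 0] <- 0
  pcs <- stats::prcomp(es, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  if (!is.null(batch)) {
    assert_that(length(batch) == nrow(e), "batch length mismatch")
    for (b in unique(batch)) {
      i <- batch == b
      pcs[i, ] <- sweep(pcs[i, , drop = FALSE], 2,
                        colMeans(pcs[i, , drop = FALSE]))
    }
  }
  k <- min(k, nrow(pcs) - 1L)
  nn <- knn_index(pcs, k)
  n <- nrow(pcs)
  ## adjacency including self so shared-neighbor counts follow the usual
  ## "neighborhood of size k+1" convention
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = c(nn, seq_len(n)), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)               # shared neighborhood counts
  jac <- methods::as(S, "TsparseMatrix")
  w <- jac@x / (2 * (k + 1L) - jac@x)      # |A n B| / |A u B|
  keep <- w >= prune & jac@i < jac@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = jac@i[keep] + 1L, to = jac@j[keep] + 1L,
               weight = w[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  stats::setNames(as.integer(igraph::membership(comm)), rownames(e))
}

#' Default cell-type marker panels
#'
#' Canonical lineage markers: EPCAM/KRT8/KRT18 (epithelial), PDGFRA/COL3A1/
#' POSTN/COL1A1/COL5A2 (fibroblast), PECAM1 and friends (endothelial),
#' CD68 module (myeloid), CD3D module (T), MS4A1 module (B).
#'
#' @return named list cell type -> marker gene vector.
#' @export
default_marker_table <- function() {
  list(
    epithelial  = c("EPCAM", "KRT8", "KRT18"),
    fibroblast  = c("PDGFRA", "COL3A1", "POSTN", "COL1A1", "COL5A2"),
    endothelial = c("PECAM1", "CLDN5", "ITGA6", "ENG", "FLT1", "CD93", "PLVAP"),
    myeloid     = c("CD68", "APOE", "APOC1", "C1QA", "C1QC"),
    T_cell      = c("CD3D", "CCL5", "TRBC2", "CD2"),
    B_cell      = c("BANK1", "CD79A", "IGHM", "MS4A1"))
}

#' Annotate clusters by marker-panel expression
#'
#' For each cluster, computes the cluster-mean expression of every gene,
#' z-scores each marker gene across clusters, averages within each panel and
#' assigns the arg-max cell type. Exact ties are broken lexicographically and
#' flagged.
#'
#' @param e expression matrix, cells x genes.
#' @param labels per-cell cluster labels.
#' @param marker_table named list cell type -> marker genes
#'   (default [default_marker_table()]).
#' @return data.frame `cluster, cell_type, score, tie`.
#' @export
annotate_markers <- function(e, labels, marker_table = default_marker_table()) {
  present <- lapply(marker_table, intersect, y = colnames(e))
  none <- names(present)[lengths(present) == 0]
  if (length(none) > 0)
    stopf("no marker genes present for: %s (missing: %s)",
          paste(none, collapse = ", "),
          paste(unlist(marker_table[none]), collapse = ", "))
  cl <- sort(unique(labels))
  cm <- do.call(rbind, lapply(cl, function(k)
    colMeans(e[labels == k, , drop = FALSE])))
  rownames(cm) <- cl
  z <- scale(cm)                       # z-score genes across clusters
  z[, is.na(attr(z, "scaled:scale")) | attr(z, "scaled:scale") == 0] <- 0
  panel <- vapply(present, function(g)
    rowMeans(z[, g, drop = FALSE]), numeric(length(cl)))
  if (length(cl) == 1L) panel <- matrix(panel, nrow = 1,
                                        dimnames = list(cl, names(present)))
  types <- sort(colnames(panel))       # lexicographic tie-break order
  panel <- panel[, types, drop = FALSE]
  best <- apply(panel, 1, which.max)
  tie <- apply(panel, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  data.frame(cluster = cl, cell_type = types[best],
             score = panel[cbind(seq_along(cl), best)], tie = tie)
}

#' Expression-bin-controlled module score
#'
#' Score = mean expression of the signature genes minus the mean of control
#' genes sampled from the same average-expression bins, per cell.
#'
#' @param e expression matrix, cells x genes.
#' @param signature character vector of signature genes (must be present).
#' @param n_bins expression bins for control matching.
#' @param n_ctrl control genes sampled per signature gene.
#' @param seed RNG seed for control sampling.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(e, signature, n_bins = 25L, n_ctrl = 100L, seed = 1L) {
  assert_that(length(signature) > 0, "empty signature")
  missing <- setdiff(signature, colnames(e))
  assert_that(length(missing) == 0, "signature genes absent: %s",
              paste(missing, collapse = ", "))
  avg <- colMeans(e)
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = n_bins, labels = FALSE))
  names(bins) <- colnames(e)
  ctrl <- with_seed(seed, {
    unlist(lapply(signature, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      sample(pool, min(n_ctrl, length(pool)))
    }))
  })
  rowMeans(e[, signature, drop = FALSE]) -
    rowMeans(e[, unique(ctrl), drop = FALSE])
}
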