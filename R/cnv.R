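## ---------------------------------------------------------------------------
## Relative CNV inference from genome-ordered expression:
## reference centering -> genome smoothing -> dynamic denoising -> [-1,1]
## rescale -> per-cell burden score. The discrete HMM segmentation lives in
## hmm.R; clone-level consensus calling in consensus.R.
## ---------------------------------------------------------------------------

#' Center expression on a copy-neutral reference population
#'
#' Drops genes whose mean expression (over all cells) is below `cutoff`,
#' subtracts the reference-cell mean per gene, optionally median-centres each
#' cell's residuals (which removes the genome-wide shift that library-size
#' normalisation induces in aneuploid cells) and clips residuals to
#' `+/- clip`.
#'
#' @param e expression matrix, cells x genes (log scale).
#' @param ref_ids reference cell ids (rows of `e`); at least `min_ref` needed.
#' @param cutoff genes with mean expression below this are dropped.
#' @param clip residual clipping bound.
#' @param center_cells subtract each cell's median residual.
#' @param min_ref minimum reference population size.
#' @return residual matrix (cells x retained genes) with attribute
#'   `ref_ids`.
#' @export
center_on_reference <- function(e, ref_ids, cutoff = 0.1, clip = 3,
                                center_cells = TRUE, min_ref = 20L) {
  assert_that(length(ref_ids) > 0, "empty reference population")
  assert_that(all(ref_ids %in% rownames(e)), "unknown reference cell ids")
  assert_that(length(ref_ids) >= min_ref,
              "need >= %d reference cells, got %d", min_ref, length(ref_ids))
  keep <- colMeans(e) >= cutoff
  if (!any(keep)) stopf("all genes below expression cutoff %.3g", cutoff)
  e <- e[, keep, drop = FALSE]
  ref_mean <- colMeans(e[ref_ids, , drop = FALSE])
  r <- sweep(e, 2, ref_mean)
  if (center_cells) r <- sweep(r, 1, apply(r, 1, stats::median))
  r <- pmin(pmax(r, -clip), clip)
  attr(r, "ref_ids") <- ref_ids
  r
}

#' Moving-average smoothing along the genome
#'
#' Replaces each value by the mean over a `window`-gene window centred on the
#' gene, within its chromosome (windows shrink at chromosome edges and never
#' cross a chromosome boundary). Columns are reordered to genome order.
#'
#' @param m residual matrix, cells x genes.
#' @param positions gene-position table covering `colnames(m)`.
#' @param window odd window size in genes; capped (with a warning) on
#'   chromosomes shorter than the window.
#' @return smoothed matrix in genome order, with attribute `chrom`
#'   (per-column chromosome).
#' @export
smooth_genome <- function(m, positions, window = 101L) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  pos <- positions[match(colnames(m), positions$gene), ]
  ord <- genome_order(pos)
  m <- m[, ord, drop = FALSE]
  pos <- pos[ord, ]
  out <- m
  for (chrom in unique(pos$chrom)) {
    j <- which(pos$chrom == chrom)
    g <- length(j)
    w <- window
    if (w > g) {
      warnf("window %d exceeds chromosome %s (%d genes); capped", w, chrom, g)
      w <- if (g %% 2 == 1) g else g - 1L
    }
    h <- (w - 1L) %/% 2L
    cs <- cbind(0, t(apply(m[, j, drop = FALSE], 1, cumsum)))
    a <- pmax(seq_len(g) - h, 1L)
    b <- pmin(seq_len(g) + h, g)
    out[, j] <- (cs[, b + 1L, drop = FALSE] - cs[, a, drop = FALSE]) /
      rep(b - a + 1L, each = nrow(m))
  }
  attr(out, "chrom") <- pos$chrom
  attr(out, "ref_ids") <- attr(m, "ref_ids")
  out
}

#' Dynamic reference-band denoising
#'
#' For each gene, values within `k_sd` standard deviations of the
#' reference-cell mean are treated as noise: the emitted signal is
#' `x - ref_mean`, set to exactly 0 inside the (closed) band. Values outside
#' the band pass through unchanged (still relative to the reference mean), so
#' increasing `k_sd` can only shrink `|signal|`.
#'
#' @param m smoothed residual matrix, cells x genes.
#' @param ref_ids reference cell ids (default: the `ref_ids` attribute).
#' @param k_sd band half-width in reference SDs.
#' @return signal matrix (same shape), attributes preserved.
#' @export
denoise_dynamic <- function(m, ref_ids = attr(m, "ref_ids"), k_sd = 1.5) {
  assert_that(!is.null(ref_ids) && all(ref_ids %in% rownames(m)),
              "reference cells not present in matrix")
  ref <- m[ref_ids, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  if (stats::sd(as.vector(ref)) == 0)
    stopf("zero reference variance; supply more/other reference cells")
  sdv[sdv == 0] <- stats::sd(as.vector(ref))  # per-gene fallback
  s <- sweep(m, 2, mu)
  s[abs(s) <= rep(k_sd * sdv, each = nrow(m))] <- 0
  attr(s, "chrom") <- attr(m, "chrom")
  attr(s, "ref_ids") <- ref_ids
  s
}

#' Rescale a denoised signal matrix to [-1, 1]
#'
#' Divides by the matrix-wide maximum absolute value (after optional
#' symmetric percentile clipping). An all-zero matrix is returned unchanged.
#'
#' @param m denoised signal matrix.
#' @param clip_percentile optional upper-tail percentile (e.g. 0.99) for
#'   symmetric clipping before rescaling; `NULL` disables clipping.
#' @return a `cnv_matrix`: the rescaled matrix with attributes `scale_factor`
#'   (the divisor), `chrom` and `ref_ids`.
#' @export
rescale_unit <- function(m, clip_percentile = NULL) {
  assert_that(all(is.finite(m)), "non-finite values in signal matrix")
  if (!is.null(clip_percentile)) {
    q <- stats::quantile(abs(m[m != 0]), clip_percentile, names = FALSE)
    m <- pmin(pmax(m, -q), q)
  }
  mx <- max(abs(m))
  out <- if (mx > 0) m / mx else m
  attr(out, "scale_factor") <- if (mx > 0) mx else 1
  attr(out, "chrom") <- attr(m, "chrom")
  attr(out, "ref_ids") <- attr(m, "ref_ids")
  class(out) <- c("cnv_matrix", class(out))
  out
}

#' Per-cell CNV burden score
#'
#' Default (`mode = "mean_abs"`) is the mean absolute rescaled signal per
#' cell: the total CNV signal normalised by gene count, so scores are
#' comparable across gene panels of different sizes. `mode = "sum_abs"`
#' returns the raw sum.
#'
#' @param x a `cnv_matrix` (or any cells x genes signal matrix).
#' @param mode `"mean_abs"` (default) or `"sum_abs"`.
#' @return named non-negative numeric vector, one score per cell.
#' @export
cnv_score <- function(x, mode = c("mean_abs", "sum_abs")) {
  mode <- match.arg(mode)
  s <- rowSums(abs(unclass(x)))
  if (mode == "mean_abs") s <- s / ncol(x)
  s
}

#' Group cells into CNV clones by hierarchical clustering
#'
#' Ward clustering on Euclidean distances between rescaled CNV profiles;
#' `k` chosen by maximum mean silhouette over `2:max_k` when not given.
#'
#' @param x a `cnv_matrix` restricted to the cells of interest.
#' @param k number of clones, or `NULL` to select by silhouette.
#' @param max_k largest k considered during selection.
#' @return integer clone labels named by cell.
#' @export
cluster_clones <- function(x, k = NULL, max_k = 8L) {
  d <- stats::dist(unclass(x))
  hc <- stats::hclust(d, method = "ward.D2")
  if (is.null(k)) {
    dm <- as.matrix(d)
    ks <- 2:min(max_k, nrow(dm) - 1L)
    sil <- vapply(ks, function(kk)
      mean_silhouette(stats::cutree(hc, kk), dm), numeric(1))
    k <- ks[which.max(sil)]
  }
  stats::cutree(hc, k)
}

## Mean silhouette width of a labelling given a distance matrix.
mean_silhouette <- function(labels, dm) {
  n <- length(labels)
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sizes[[as.character(labels[i])]] > 1)
      sum(dm[i, own]) / (sizes[[as.character(labels[i])]] - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dm[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Average rows of a signal matrix by group (clone) label
#'
#' @param x cells x genes matrix (e.g. a `cnv_matrix` or residuals).
#' @param labels named vector cell -> group covering `rownames(x)`.
#' @return groups x genes matrix, attributes (`chrom`, class) preserved.
#' @export
clone_profiles <- function(x, labels) {
  labels <- labels[rownames(x)]
  assert_that(!anyNA(labels), "labels missing for some cells")
  m <- rowsum(unclass(x), labels) / as.vector(table(labels))
  attr(m, "chrom") <- attr(x, "chrom")
  m
}

#' Run the full per-sample CNV inference chain
#'
#' For each sample: log-normalise, drop mitochondrial genes, centre on that
#' sample's reference cells, smooth along the genome, denoise, rescale and
#' score. Reference cells must be flagged in `x$cells$is_reference`.
#'
#' @param x a `cohort`.
#' @param cutoff,window,k_sd,clip,scale pipeline parameters (see the stage
#'   functions).
#' @param center_cells passed to [center_on_reference()].
#' @return named list per sample, each with elements `cnv` (cnv_matrix),
#'   `score` (per-cell burden), `residuals` (unsmoothed centred residuals,
#'   for boundary refinement), `sigma_ref` (reference SD of the smoothed
#'   signal on the rescaled scale) and `positions`.
#' @export
infer_cnv <- function(x, cutoff = 0.1, window = 101L, k_sd = 1.5,
                      clip = 3, scale = 1e4, center_cells = TRUE) {
  keep_genes <- x$genes$gene[!is_mito_gene(x$genes)]
  out <- list()
  for (s in unique(x$cells$sample)) {
    cells <- x$cells$cell[x$cells$sample == s]
    sub <- subset_cohort(x, cells = cells, genes = keep_genes)
    e <- normalize_log1p(sub, scale = scale)
    ref <- sub$cells$cell[sub$cells$is_reference]
    r <- center_on_reference(e, ref, cutoff = cutoff, clip = clip,
                             center_cells = center_cells)
    sm <- smooth_genome(r, sub$genes, window = window)
    den <- denoise_dynamic(sm, ref, k_sd = k_sd)
    cnv <- rescale_unit(den)
    fac <- attr(cnv, "scale_factor")
    sigma_ref <- stats::sd(sm[ref, , drop = FALSE]) / fac
    pos <- sub$genes[match(colnames(sm), sub$genes$gene), ]
    out[[s]] <- list(cnv = cnv, score = cnv_score(cnv),
                     residuals = r[, colnames(sm), drop = FALSE],
                     sigma_ref = sigma_ref, positions = pos)
  }
  out
}
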