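## ---------------------------------------------------------------------------
## Three-state HMM segmentation of genome-ordered CNV signal.
## States: deletion (mu = -delta), neutral (mu = 0), amplification (+delta),
## Gaussian emissions with shared sigma, symmetric transitions with
## self-transition probability p_stay. Viterbi per chromosome, vectorised
## over cells. Optional least-squares changepoint refinement of region
## boundaries against unsmoothed residuals (the moving average blurs edges
## by ~window/2 genes; the refinement undoes that).
## ---------------------------------------------------------------------------

## Vectorised Viterbi for one chromosome. x: cells x genes. Returns an
## integer matrix of state indices (1 = del, 2 = neutral, 3 = amp).
## Ties break toward the lower state index (deterministic).
viterbi3 <- function(x, delta, sigma, p_stay) {
  assert_that(sigma > 0, "HMM emission sigma is zero; cannot segment")
  n <- nrow(x); g <- ncol(x)
  mu <- c(-delta, 0, delta)
  ltr <- matrix(log((1 - p_stay) / 2), 3, 3)
  diag(ltr) <- log(p_stay)
  ll <- function(j, s) stats::dnorm(x[, j], mu[s], sigma, log = TRUE)
  V <- vapply(1:3, function(s) log(1 / 3) + ll(1, s), numeric(n))
  if (n == 1L) V <- matrix(V, 1)
  ptr <- array(0L, c(n, 3, g))
  for (j in seq_len(g)[-1]) {
    Vn <- matrix(0, n, 3)
    for (s in 1:3) {
      cand <- sweep(V, 2, ltr[, s], `+`)
      best <- max.col(cand, ties.method = "first")
      ptr[, s, j] <- best
      Vn[, s] <- cand[cbind(seq_len(n), best)] + ll(j, s)
    }
    V <- Vn
  }
  path <- matrix(0L, n, g)
  path[, g] <- max.col(V, ties.method = "first")
  for (j in rev(seq_len(g - 1L)))
    path[, j] <- ptr[cbind(seq_len(n), path[, j + 1L], j + 1L)]
  path
}

## Least-squares single-changepoint index in y (split after position t).
changepoint_ls <- function(y) {
  s <- cumsum(y - mean(y))
  which.max(abs(s[-length(s)]))
}

## Refine one boundary of a region by changepoint detection on the raw
## residuals y (one chromosome). Returns the new boundary gene index.
refine_boundary <- function(y, boundary, side, lo_lim, hi_lim, margin) {
  if (side == "left") {
    a <- max(lo_lim, boundary - margin)
    b <- min(hi_lim, boundary + margin)
    if (b - a < 3) return(boundary)
    a + changepoint_ls(y[a:b])
  } else {
    a <- max(lo_lim, boundary - margin)
    b <- min(hi_lim, boundary + margin)
    if (b - a < 3) return(boundary)
    a + changepoint_ls(y[a:b]) - 1L
  }
}

#' Call discrete CNV regions with a three-state HMM
#'
#' Runs a Viterbi decoding per chromosome (deletion / neutral /
#' amplification; Gaussian emissions with shared `sigma`; symmetric
#' transition matrix with self-transition `p_stay`), merges consecutive
#' same-state genes into regions and drops neutral regions. With
#' `refine = TRUE` each emitted boundary that is interior to its chromosome
#' is re-estimated by a least-squares changepoint fit on `refine_on`
#' (typically the unsmoothed residual matrix), undoing moving-average blur.
#'
#' @param x signal matrix, cells (or clone profiles) x genes, in genome
#'   order; typically a `cnv_matrix`.
#' @param positions gene-position table covering `colnames(x)`.
#' @param sigma shared emission SD. Default: SD of the reference-cell rows
#'   (attribute `ref_ids`); an error if that is zero.
#' @param delta amplitude of the non-neutral state means; scalar or one
#'   value per row. Default: the median absolute signal over genes surviving
#'   denoising, matrix-wide (fallback 0.2 when nothing survives).
#' @param p_stay self-transition probability.
#' @param refine refine boundaries by changepoint detection.
#' @param refine_on matrix used for refinement (defaults to `x`).
#' @param refine_margin search half-width in genes around each boundary.
#' @return data.frame of calls: `cell, chrom, start_gene, end_gene`
#'   (1-based inclusive indices within chromosome), `start_idx, end_idx`
#'   (global genome-order column indices), `start, end` (genomic, 1-based
#'   inclusive), `state` (`"deletion"`/`"amplification"`), `mean_signal`,
#'   `n_genes`.
#' @export
call_states_hmm <- function(x, positions, sigma = NULL, delta = NULL,
                            p_stay = 0.99, refine = FALSE, refine_on = NULL,
                            refine_margin = 60L) {
  x <- as.matrix(x)
  assert_that(!is.null(rownames(x)), "signal matrix needs row names")
  pos <- positions[match(colnames(x), positions$gene), ]
  assert_that(!anyNA(pos$gene), "positions missing for some genes")
  ord <- genome_order(pos)
  assert_that(all(ord == seq_along(ord)),
              "signal matrix must be in genome order (use smooth_genome)")
  if (is.null(sigma)) {
    ref <- attr(x, "ref_ids")
    assert_that(!is.null(ref), "supply sigma or a matrix with ref_ids")
    sigma <- stats::sd(x[intersect(ref, rownames(x)), , drop = FALSE])
  }
  assert_that(is.numeric(sigma) && sigma > 0,
              "sigma = 0: reference residuals carry no variance")
  if (is.null(delta)) {
    nz <- abs(x[x != 0])  # genes surviving denoising, matrix-wide
    delta <- if (length(nz) > 0) stats::median(nz) else 0.2
    if (!is.finite(delta) || delta == 0) delta <- 0.2
  }
  delta <- rep(delta, length.out = nrow(x))
  if (!is.null(refine_on)) refine_on <- as.matrix(refine_on)

  calls <- list()
  for (chrom in unique(pos$chrom)) {
    j <- which(pos$chrom == chrom)
    xg <- x[, j, drop = FALSE]
    ## group rows by delta so each group is decoded in one vectorised pass
    for (dv in unique(delta)) {
      rows <- which(delta == dv)
      path <- viterbi3(xg[rows, , drop = FALSE], dv, sigma, p_stay)
      for (ri in seq_along(rows)) {
        p <- path[ri, ]
        r <- rle(p)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        segs <- which(r$values != 2L)
        for (si in seq_along(segs)) {
          seg <- segs[si]
          lo <- starts[seg]; hi <- ends[seg]
          if (refine) {
            y <- if (is.null(refine_on)) xg[rows[ri], ] else
              refine_on[rows[ri], j]
            mid <- (lo + hi) %/% 2L
            ## never search past a neighbouring called segment, whose raw
            ## residuals would distort the changepoint fit
            lo_lim <- if (si > 1L) ends[segs[si - 1L]] + 1L else 1L
            hi_lim <- if (si < length(segs)) starts[segs[si + 1L]] - 1L
                      else length(j)
            if (lo > 1L)
              lo <- refine_boundary(y, lo, "left", lo_lim, mid, refine_margin)
            if (hi < length(j))
              hi <- refine_boundary(y, hi, "right", mid, hi_lim,
                                    refine_margin)
            if (lo > hi) next
          }
          calls[[length(calls) + 1L]] <- data.frame(
            cell = rownames(x)[rows[ri]], chrom = chrom,
            start_gene = lo, end_gene = hi,
            start_idx = j[lo], end_idx = j[hi],
            start = pos$start[j[lo]], end = pos$end[j[hi]],
            state = if (r$values[seg] == 3L) "amplification" else "deletion",
            mean_signal = mean(xg[rows[ri], starts[seg]:ends[seg]]),
            n_genes = hi - lo + 1L)
        }
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(cell = character(0), chrom = character(0),
                      start_gene = integer(0), end_gene = integer(0),
                      start_idx = integer(0), end_idx = integer(0),
                      start = integer(0), end = integer(0),
                      state = character(0), mean_signal = numeric(0),
                      n_genes = integer(0)))
  out <- do.call(rbind, calls)
  out[order(out$cell, match(out$chrom, unique(pos$chrom)), out$start_gene), ,
      drop = FALSE]
}

#' Write region calls as a BED-like TSV
#'
#' Genomic coordinates are converted from the internal 1-based inclusive
#' representation to BED's 0-based half-open convention.
#'
#' @param calls output of [call_states_hmm()] or consensus events.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                    end = calls$end, name = calls$cell,
                    state = calls$state)
  write_tsv(bed, path)
}
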