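## ---------------------------------------------------------------------------
## Malignant-cell identification: 1-D k-means on CNV burden scores (k = 3);
## the cluster with the highest mean score is labelled tumor, everything
## else unassigned. Specificity over sensitivity: only the top cluster is
## tumor even when the middle cluster is borderline.
## ---------------------------------------------------------------------------

#' Exact one-dimensional k-means
#'
#' Optimal 1-D clusters are contiguous in sorted order, so the global
#' minimum of the within-cluster sum of squares is found exactly by dynamic
#' programming over sorted split points — fully deterministic, no random
#' restarts. Clusters are reported in increasing-center order, so cluster
#' `k` always holds the largest scores; ties in the DP break toward the
#' earliest split (equivalently, toward the lower cluster index).
#'
#' @param scores numeric vector; needs at least `k` distinct values.
#' @param k number of clusters.
#' @return list with `cluster` (per-score index, named like `scores`),
#'   `centers` (increasing), `withinss` (total within-cluster sum of
#'   squares).
#' @export
kmeans1d <- function(scores, k = 3L) {
  assert_that(length(unique(scores)) >= k,
              "need at least %d distinct score values, got %d",
              k, length(unique(scores)))
  o <- order(scores)
  x <- scores[o]
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  ssq_vec <- function(i, j)  # within-SS of x[i..j], vectorised over i
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / (j - i + 1)
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)  # start index of the last cluster
  j1 <- seq_len(n)
  D[1, ] <- (cs2[j1 + 1] - cs2[1]) - (cs[j1 + 1] - cs[1])^2 / j1
  B[1, ] <- 1L
  for (kk in 2:k) for (j in kk:n) {
    m <- (kk - 1):(j - 1)                    # last cluster = x[(m+1)..j]
    cost <- D[kk - 1, m] + ssq_vec(m + 1, j)
    best <- which.min(cost)
    D[kk, j] <- cost[best]
    B[kk, j] <- m[best] + 1L
  }
  lab_sorted <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- B[kk, j]
    lab_sorted[i:j] <- kk
    j <- i - 1L
  }
  cl <- integer(n)
  cl[o] <- lab_sorted
  centers <- vapply(seq_len(k), function(i) mean(scores[cl == i]), numeric(1))
  list(cluster = stats::setNames(cl, names(scores)),
       centers = centers,
       withinss = D[k, n])
}

#' Label the top-scoring cluster as tumor
#'
#' @param assignment output of [kmeans1d()] (or a compatible list with
#'   `cluster`).
#' @param scores the scores that were clustered.
#' @return list with `label` (per-cell `"tumor"`/`"unassigned"`, named),
#'   `tumor_cluster`, `cluster_means`, `cluster_sizes`.
#' @export
label_tumor <- function(assignment, scores) {
  cl <- assignment$cluster
  ks <- sort(unique(cl))
  means <- vapply(ks, function(i) mean(scores[cl == i]), numeric(1))
  top <- max(means)
  if (sum(abs(means - top) < 1e-12) > 1)
    stopf("two clusters tie on mean score (within 1e-12); manual review needed")
  tumor <- ks[which.max(means)]
  list(label = stats::setNames(ifelse(cl == tumor, "tumor", "unassigned"),
                               names(cl)),
       tumor_cluster = tumor,
       cluster_means = stats::setNames(means, ks),
       cluster_sizes = stats::setNames(
         vapply(ks, function(i) sum(cl == i), integer(1)), ks))
}

#' Classify cells as tumor vs unassigned from CNV scores, per sample
#'
#' Convenience wrapper: runs [kmeans1d()] (k = 3) and [label_tumor()]
#' within each sample, as the per-sample analysis requires.
#'
#' @param scores named per-cell scores.
#' @param sample per-cell sample labels aligned with `scores`.
#' @param k clusters per sample.
#' @return data.frame `cell, sample, score, cluster, label`.
#' @export
classify_malignant <- function(scores, sample, k = 3L) {
  out <- lapply(unique(sample), function(s) {
    sc <- scores[sample == s]
    lab <- label_tumor(km <- kmeans1d(sc, k = k), sc)
    data.frame(cell = names(sc), sample = s, score = unname(sc),
               cluster = unname(km$cluster), label = unname(lab$label))
  })
  do.call(rbind, out)
}
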