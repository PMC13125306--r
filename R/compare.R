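## ---------------------------------------------------------------------------
## Cross-sample / cross-histology statistics: Venn-style set decomposition,
## rank-sum burden comparison, expression-score correlation.
## ---------------------------------------------------------------------------

#' Exact subset decomposition of item sets (Venn analysis)
#'
#' Decomposes the union of the input sets by membership pattern, so every
#' union element lands in exactly one cell of the decomposition; the
#' universal intersection is highlighted. Works for gene symbols and for
#' cytoband region strings alike.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return an `overlap_result`: list with `decomposition` (named list,
#'   pattern like `"A&B"` -> items), `counts`, `intersection`, `union_size`.
#' @export
overlap_sets <- function(sets) {
  assert_that(length(sets) >= 2, "need at least 2 sets")
  assert_that(!is.null(names(sets)) && !anyDuplicated(names(sets)),
              "sets must be uniquely named")
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  decomposition <- split(universe, pattern)
  all_key <- paste(names(sets), collapse = "&")
  structure(list(decomposition = decomposition,
                 counts = lengths(decomposition),
                 intersection = decomposition[[all_key]] %||% character(0),
                 union_size = length(universe)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> union %d items, %d shared by all sets\n",
              x$union_size, length(x$intersection)))
  invisible(x)
}

#' Two-sided Wilcoxon / Mann-Whitney rank-sum test
#'
#' Uses exact enumeration of all rank assignments when `n1 + n2 <= 20`
#' (ties handled by enumeration over midranks; two-sided p is the
#' permutation probability of a U statistic at least as far from its null
#' mean), and the tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param exact force or forbid exact enumeration (default: by size).
#' @return list with `statistic` (Mann-Whitney U of `group_a`), `p.value`,
#'   `method`.
#' @export
wilcoxon_compare <- function(group_a, group_b, exact = NULL) {
  n1 <- length(group_a); n2 <- length(group_b)
  assert_that(n1 > 0 && n2 > 0, "both groups must be non-empty")
  if (is.null(exact)) exact <- (n1 + n2) <= 20
  r <- rank(c(group_a, group_b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    corr <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    v <- n1 * n2 / 12 * (n1 + n2 + 1 - corr)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = u_obs, p.value = p, method = method)
}

#' Correlate per-cell expression with CNV score
#'
#' @param expr,score paired numeric vectors (>= 10 pairs, non-constant).
#' @param method `"spearman"` (default; robust to the heavy-tailed score
#'   distribution) or `"pearson"`.
#' @return list with `r`, `p.value`, `method`, `n`.
#' @export
correlate_expr_score <- function(expr, score,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_that(length(expr) == length(score), "length mismatch")
  assert_that(length(expr) >= 10, "need >= 10 paired observations")
  assert_that(stats::sd(expr) > 0 && stats::sd(score) > 0,
              "constant input vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(expr, score, method = method))
  list(r = unname(ct$estimate), p.value = ct$p.value, method = method,
       n = length(expr))
}
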