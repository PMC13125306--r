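## Independent oracles used to freeze expected values. These deliberately
## avoid the code paths they check.

## Brute-force Viterbi: enumerate all 3^g state paths for a single profile.
viterbi_brute <- function(x, delta, sigma, p_stay) {
  g <- length(x)
  mu <- c(-delta, 0, delta)
  ltr <- matrix(log((1 - p_stay) / 2), 3, 3)
  diag(ltr) <- log(p_stay)
  paths <- as.matrix(expand.grid(rep(list(1:3), g)))
  best <- -Inf; best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(1 / 3) + sum(dnorm(x, mu[p], sigma, log = TRUE))
    if (g > 1) lp <- lp + sum(ltr[cbind(p[-g], p[-1])])
    if (lp > best) { best <- lp; best_path <- p }
  }
  unname(best_path)
}

## Exact 1-D k-means by dynamic programming over sorted splits (optimal 1-D
## clusters are contiguous in sorted order). Returns the optimal total
## within-cluster sum of squares.
kmeans1d_dp <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {  # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- ssq(1, j)
  for (kk in 2:k) for (j in kk:n)
    dp[kk, j] <- min(vapply((kk - 1):(j - 1), function(m)
      dp[kk - 1, m] + ssq(m + 1, j), numeric(1)))
  dp[k, n]
}

## Membership-bitmask tally of a set decomposition.
bitmask_decomposition <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  mask <- vapply(universe, function(it)
    paste(names(sets)[vapply(sets, function(s) it %in% s, logical(1))],
          collapse = "&"), character(1))
  table(mask)
}

## Adjusted Rand index.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## Log-rank p for one dichotomization via survival::survdiff (scan oracle).
survdiff_p <- function(time, event, grp) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
}
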