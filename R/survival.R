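## ---------------------------------------------------------------------------
## Survival machinery: Kaplan-Meier + log-rank, maximally selected
## expression cutpoint (with honest selection-bias reporting), univariate
## Cox. KM/log-rank/Cox are backed by the survival package; the cutpoint
## scan is a vectorised log-rank score test over all admissible
## dichotomizations, cross-checked against survival::survdiff in the tests.
## ---------------------------------------------------------------------------

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time,event survival times (>= 0) and event indicators (0/1).
#' @param group per-subject group labels (>= 2 groups).
#' @return list with `curves` (data.frame `group, time, n_risk, n_event,
#'   survival`), `chisq`, `df`, `p.value`.
#' @export
km_logrank <- function(time, event, group) {
  assert_that(all(time >= 0), "negative survival time")
  assert_that(sum(event) >= 1, "no events: nothing to test")
  g <- factor(group)
  assert_that(nlevels(g) >= 2, "need at least two groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sm <- summary(fit)
  curves <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  list(curves = curves, chisq = sd$chisq, df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

## Vectorised two-group log-rank chi-square for every cutpoint at once.
## Returns per-cutpoint chisq (NA where the variance degenerates).
logrank_scan <- function(time, event, expr, cuts) {
  dt <- sort(unique(time[event == 1]))
  R <- outer(time, dt, `>=`)                    # at risk
  D <- outer(time, dt, `==`) & (event == 1)     # died at t
  G <- outer(expr, cuts, `>`)                   # high-expression arm
  n_j <- colSums(R); d_j <- colSums(D)
  n1 <- crossprod(R, G)                         # at-risk in high arm
  d1 <- crossprod(D, G)
  U <- colSums(d1 - d_j * n1 / n_j)
  vf <- d_j * (n_j - d_j) / pmax(n_j - 1, 1)
  V <- colSums(vf * (n1 / n_j) * (1 - n1 / n_j))
  chisq <- ifelse(V > 0, U^2 / V, NA_real_)
  chisq
}

#' Maximally selected survival cutpoint
#'
#' Scans every distinct expression value inside the `band` percentile
#' window (both arms at least `min_per_arm` subjects), computes the
#' two-group log-rank p for each dichotomization at `expression > cut`, and
#' returns the minimizer. The naive minimum p is selection-biased, so a
#' permutation-adjusted p (min-p null distribution over `n_perm` seeded
#' permutations of the expression values) is reported alongside it.
#'
#' @param time,event survival data.
#' @param expr per-subject expression values.
#' @param band admissible percentile window for candidate cutpoints.
#' @param min_per_arm minimum subjects per arm.
#' @param n_perm permutations for the adjusted p (0 disables).
#' @param seed RNG seed for the permutations.
#' @return list with `cutpoint`, `p.value` (naive minimum), `p.adjusted`
#'   (permutation; `NA` when `n_perm = 0`), `chisq`, `groups` (per-subject
#'   `"high"`/`"low"`), `scan` (data.frame `cut, chisq, p`).
#' @export
best_cutpoint <- function(time, event, expr, band = c(0.1, 0.9),
                          min_per_arm = 10L, n_perm = 1000L, seed = 1L) {
  assert_that(sum(event) >= 1, "no events")
  q <- stats::quantile(expr, band, names = FALSE)
  cuts <- sort(unique(expr))
  cuts <- cuts[cuts >= q[1] & cuts <= q[2]]
  nhigh <- vapply(cuts, function(c2) sum(expr > c2), integer(1))
  cuts <- cuts[nhigh >= min_per_arm & (length(expr) - nhigh) >= min_per_arm]
  assert_that(length(cuts) > 0,
              "no admissible cutpoint (constant expression or arms too small)")
  chisq <- logrank_scan(time, event, expr, cuts)
  ok <- !is.na(chisq)
  assert_that(any(ok), "log-rank degenerate at every candidate cutpoint")
  p <- stats::pchisq(chisq, 1, lower.tail = FALSE)
  best <- which.min(ifelse(ok, p, Inf))
  p_adj <- NA_real_
  if (n_perm > 0) {
    obs <- p[best]
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        ep <- sample(expr)
        cp <- stats::pchisq(logrank_scan(time, event, ep, cuts), 1,
                            lower.tail = FALSE)
        min(cp, na.rm = TRUE) <= obs
      }, logical(1)))
    })
    p_adj <- (1 + hits) / (n_perm + 1)
  }
  list(cutpoint = cuts[best], p.value = p[best], p.adjusted = p_adj,
       chisq = chisq[best],
       groups = ifelse(expr > cuts[best], "high", "low"),
       scan = data.frame(cut = cuts, chisq = chisq, p = p))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood estimate with a Wald confidence interval; the hazard
#' ratio is `exp(beta)`. Monotone-likelihood / separation is flagged (no
#' silent estimate is returned).
#'
#' @param time,event survival data (>= `min_events` events).
#' @param covariate numeric covariate (non-constant).
#' @param conf_level Wald CI level.
#' @param min_events minimum number of events.
#' @return list with `hr`, `ci` (length 2), `p.value`, `beta`, `se`,
#'   `flagged` (TRUE when the likelihood is monotone; estimates are `NA`).
#' @export
cox_univariate <- function(time, event, covariate, conf_level = 0.95,
                           min_events = 10L) {
  assert_that(stats::sd(covariate) > 0, "constant covariate")
  assert_that(sum(event) >= min_events,
              "need >= %d events, got %d", min_events, sum(event))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (warned || !is.finite(beta) || se > 50 || abs(beta) > 20)
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                p.value = NA_real_, beta = beta, se = se, flagged = TRUE))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * z * se),
       p.value = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se,
       flagged = FALSE)
}
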