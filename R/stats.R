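#' Paired / one-sample t test on within-participant contrasts
#'
#' `t = mean / (SD / sqrt(n))` with `df = n - 1`, two-tailed p from the t
#' distribution, and the standardized within-participant effect size
#' `dz = mean / SD`.
#'
#' @param diffs Numeric vector of per-participant differences (n >= 2,
#'   nonzero SD).
#' @return List with `t`, `df`, `p`, `dz`, `n`, `mean`.
#' @export
paired_t <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2) stopf("need n >= 2")
  s <- sd(diffs)
  if (s == 0) stopf("zero standard deviation")
  t <- mean(diffs) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
       dz = mean(diffs) / s, n = n, mean = mean(diffs))
}

#' Combine effect sizes across experiments
#'
#' Fixed-effect inverse-variance-weighted mean of Cohen's d values, with the
#' one-sample approximation `Var(d) = 1/n + d^2 / (2n)`; an unweighted mean
#' is also available.
#'
#' @param effects Data frame with columns `d` and `n` (participants).
#' @param method `"fixed_inverse_variance"` (default) or `"unweighted"`.
#' @return List with `d` (combined), `se` (for the fixed-effect method) and
#'   `method`.
#' @export
combine_effects <- function(effects,
                            method = c("fixed_inverse_variance",
                                       "unweighted")) {
  method <- match.arg(method)
  stopifnot(all(c("d", "n") %in% names(effects)))
  if (nrow(effects) < 2) stopf("need >= 2 effect records")
  if (any(!is.finite(effects$n))) stopf("missing n")
  if (method == "unweighted")
    return(list(d = mean(effects$d), se = NA_real_, method = method))
  v <- 1 / effects$n + effects$d^2 / (2 * effects$n)
  w <- 1 / v
  list(d = sum(w * effects$d) / sum(w), se = sqrt(1 / sum(w)),
       method = method)
}

#' Sample size for replicating a within-participant effect
#'
#' Normal-approximation sample size for a one-sample (paired) t test:
#' `n = ceiling(((z_{1-alpha/tails} + z_{power}) / d)^2)`, minimum 2. The
#' exact noncentral-t method (`method = "noncentral_t"`, via
#' [stats::power.t.test()]) is more conservative and never returns fewer
#' participants than the normal approximation.
#'
#' @param d Within-participant Cohen's dz (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 1 or 2 (default 2).
#' @param method `"normal_approx"` (default) or `"noncentral_t"`.
#' @return Integer sample size.
#' @export
sample_size <- function(d, alpha = 0.05, power = 0.80, tails = 2,
                        method = c("normal_approx", "noncentral_t")) {
  method <- match.arg(method)
  if (d <= 0) stopf("d must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stopf("alpha and power must lie in (0, 1)")
  if (method == "normal_approx") {
    n <- ceiling(((qnorm(1 - alpha / tails) + qnorm(power)) / d)^2)
    return(max(n, 2L))
  }
  pw <- power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                     type = "one.sample",
                     alternative = if (tails == 1) "one.sided"
                                   else "two.sided")
  max(ceiling(pw$n), 2L)
}

#' Correlation between resting motor threshold and effect size
#'
#' Pearson correlation across participants between RMT and a per-participant
#' effect measure, with `df = n - 2` and a two-tailed p value.
#'
#' @param rmt,effect Numeric vectors (paired, n >= 3).
#' @return List with `r`, `df`, `p`, `n`.
#' @export
rmt_effect_correlation <- function(rmt, effect) {
  ok <- complete.cases(rmt, effect)
  rmt <- rmt[ok]; effect <- effect[ok]
  n <- length(rmt)
  if (n < 3) stopf("need n >= 3")
  if (sd(rmt) == 0 || sd(effect) == 0) stopf("zero variance")
  r <- cor(rmt, effect)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, df = n - 2, p = 2 * pt(-abs(t), n - 2), n = n)
}

#' Detection rate as a percentage
#'
#' Convenience for reporting counts such as rater MEP detections:
#' `100 * n / total`, rounded to one decimal place.
#'
#' @param n,total Counts.
#' @return Percentage (one decimal).
#' @export
detection_percent <- function(n, total) {
  if (total <= 0) stopf("total must be > 0")
  round(100 * n / total, 1)
}
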