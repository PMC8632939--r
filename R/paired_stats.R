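# Effect sizes, confidence intervals and correlations for the paired and
# two-group comparisons.
#
# Conventions: d is reported as an absolute magnitude (the signed mean
# difference is carried separately); confidence intervals for d use the
# large-sample normal approximation with SE(d) = sqrt(1/n + d^2/(2n)) for
# the paired design and SE(d) = sqrt((n1+n2)/(n1 n2) + d^2/(2(n1+n2))) for
# two groups; p-values are two-sided; the two-group test pools variances
# (consistent with the pooled-SD d).

new_effect_estimate <- function(d, ci_low, ci_high, t, df, p, level, design,
                                mean_diff, sd_diff, n = NULL, n1 = NULL, n2 = NULL) {
  structure(
    list(d = d, ci_low = ci_low, ci_high = ci_high, t = t, df = df, p = p,
         level = level, design = design, mean_diff = mean_diff,
         sd_diff = sd_diff, n = n, n1 = n1, n2 = n2),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  ns <- if (x$design == "paired") sprintf("n = %d", x$n) else
    sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
  cat(sprintf("%s Cohen's d = %.*f [%d%% CI %.*f; %.*f], t(%g) = %.*f, p = %.3g (%s)\n",
              x$design, digits, x$d, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high, x$df, digits, x$t, x$p, ns))
  invisible(x)
}

#' Cohen's d from a printed mean difference and SD
#'
#' The paired-design standardized effect `|mean_diff| / sd_diff`, useful
#' for recomputing published effect sizes from summary tables.
#'
#' @param mean_diff Mean of the paired differences (score units).
#' @param sd_diff Standard deviation of the paired differences (> 0).
#' @return The absolute standardized effect (dimensionless).
#' @export
#' @examples
#' d_from_summary(-1.83, 2.44) # 0.75
d_from_summary <- function(mean_diff, sd_diff) {
  if (!is.numeric(mean_diff) || !is.numeric(sd_diff))
    abort("`mean_diff` and `sd_diff` must be numeric.")
  if (any(sd_diff <= 0)) abort("`sd_diff` must be positive.")
  abs(mean_diff) / sd_diff
}

#' Paired (within-subject) effect estimate
#'
#' One-sample analysis of a vector of paired differences: Cohen's d
#' (`|mean|/SD`, sample SD with n-1), the paired t statistic, a two-sided
#' p-value, and a normal-approximation confidence interval for d.
#'
#' @param diffs Numeric vector of paired differences, `n >= 3`, nonzero
#'   variance.
#' @param level Confidence level (default 0.99).
#' @return An `effect_estimate` (see [tidy.effect_estimate()]).
#' @export
#' @examples
#' paired_effect(c(-2, -1, -3, -2))
paired_effect <- function(diffs, level = 0.99) {
  check_prob_level(level)
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 3 || anyNA(diffs)) abort("`diffs` must have n >= 3 complete values.")
  s <- sd(diffs)
  if (s <= 0) abort("`diffs` has zero variance.")
  m <- mean(diffs)
  d <- abs(m) / s
  t_stat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  se_d <- sqrt(1 / n + d^2 / (2 * n))
  z <- qnorm(1 - (1 - level) / 2)
  new_effect_estimate(d, d - z * se_d, d + z * se_d, t_stat, n - 1, p, level,
                      "paired", mean_diff = m, sd_diff = s, n = n)
}

#' Two-group effect estimate from summary statistics
#'
#' Pooled-SD Cohen's d with the pooled-variance t test and a
#' normal-approximation confidence interval.
#'
#' @param m1,s1,n1 Mean, SD (> 0) and size of group 1.
#' @param m2,s2,n2 Mean, SD (> 0) and size of group 2.
#' @param level Confidence level (default 0.99).
#' @return An `effect_estimate`.
#' @export
#' @examples
#' two_sample_effect(-1.61, 2.45, 1010, -1.05, 2.57, 688) # d = 0.22
two_sample_effect <- function(m1, s1, n1, m2, s2, n2, level = 0.99) {
  check_prob_level(level)
  for (v in list(s1 = s1, s2 = s2))
    if (!is.numeric(v) || v <= 0) abort("Group SDs must be positive.")
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  d <- abs(m1 - m2) / sp
  t_stat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t_stat), df = df)
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - level) / 2)
  new_effect_estimate(d, d - z * se_d, d + z * se_d, t_stat, df, p, level,
                      "two_sample", mean_diff = m1 - m2, sd_diff = sp,
                      n1 = n1, n2 = n2)
}

#' One-sample deviation-from-zero profile
#'
#' Tests whether a summarised mean differs from zero (no change):
#' one-sample t test from `mean`, `sd`, `n`, with `d = |mean|/sd` and a
#' significance flag at `alpha`.
#'
#' @param mean,sd,n Summary statistics (`sd > 0`, `n >= 3`).
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: `d`, `t`, `df`, `p`, `significant`.
#' @export
#' @examples
#' one_sample_profile(-0.09, 1.96, 958) # not significant at 0.01
one_sample_profile <- function(mean, sd, n, alpha = 0.01) {
  if (!is.numeric(sd) || sd <= 0) abort("`sd` must be positive.")
  if (n < 3) abort("`n` must be at least 3.")
  check_number(alpha, "alpha", lower = 0, upper = 1)
  t_stat <- mean / (sd / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  tibble::tibble(d = abs(mean) / sd, t = t_stat, df = n - 1, p = p,
                 significant = p < alpha)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, nonzero variance.
#' @param level Confidence level (default 0.99).
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_r_ci <- function(x, y, level = 0.99) {
  check_prob_level(level)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 4 || anyNA(x) || anyNA(y)) abort("Need n >= 4 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("`x` and `y` must have nonzero variance.")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    lo <- hi <- r
  } else {
    z <- atanh(r)
    half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
    lo <- tanh(z - half)
    hi <- tanh(z + half)
  }
  tibble::tibble(r = r, ci_low = lo, ci_high = hi, n = n)
}

#' Per-emotion paired summary of a cohort
#'
#' The full change battery for each of the nine emotions: phase means and
#' SDs, the phase-1/phase-2 Pearson correlation with CI, the mean and SD of
#' the change scores, the paired Cohen's d with CI, and the JZS Bayes
#' factor (reported primarily as `log10_bf10`).
#'
#' @param cohort A `paired_cohort` from [merge_phases()].
#' @param level Confidence level for all intervals (default 0.99).
#' @param prior_scale Cauchy prior scale for the Bayes factor (default
#'   `sqrt(2)/2`).
#' @return A `paired_summary` tibble with one row per emotion.
#' @export
paired_summary <- function(cohort, level = 0.99, prior_scale = sqrt(2) / 2) {
  emo <- emotion_names()
  rows <- lapply(emo, function(e) {
    x1 <- cohort[[paste0(e, "_1")]]
    x2 <- cohort[[paste0(e, "_2")]]
    eff <- paired_effect(x2 - x1, level = level)
    rr <- pearson_r_ci(x1, x2, level = level)
    bf <- jzs_bf_one_sample(eff$t, eff$n, prior_scale = prior_scale)
    tibble::tibble(
      emotion = e,
      mean_1 = mean(x1), sd_1 = sd(x1),
      mean_2 = mean(x2), sd_2 = sd(x2),
      r = rr$r, r_low = rr$ci_low, r_high = rr$ci_high,
      mean_diff = eff$mean_diff, sd_diff = eff$sd_diff,
      d = eff$d, d_low = eff$ci_low, d_high = eff$ci_high,
      t = eff$t, p = eff$p,
      log10_bf10 = bf$log10_bf10, bf10 = bf$bf10,
      n = eff$n
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("paired_summary", class(out))
  out
}
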