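# Group summaries, confidence intervals, and normality-routed comparisons.

#' Confidence interval from mean, SEM, and n
#'
#' Computes `mean +/- q * sem` with q either the standard-normal 0.975
#' quantile (`"normal_z"`, 1.96 at the default 95% level) or the Student-t
#' 0.975 quantile at n - 1 degrees of freedom (`"student_t"`). Both rules
#' are first-class because published small-n intervals are computed by
#' either convention; pick per call.
#'
#' @param mean group mean.
#' @param sem standard error of the mean (>= 0).
#' @param n number of observations (>= 2 for `"student_t"`).
#' @param level confidence level in (0, 1); default 0.95.
#' @param method `"normal_z"` (default) or `"student_t"`.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @examples
#' confidenceInterval(104, 6.7, 10)                       # 90.87, 117.13
#' confidenceInterval(46, 2.44, 5, method = "student_t")  # 39.2, 52.8
#' @export
confidenceInterval <- function(mean, sem, n, level = 0.95,
                               method = c("normal_z", "student_t")) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be a single number in (0, 1)")
  if (sem < 0) stop("sem must be >= 0")
  q <- switch(method,
    normal_z = stats::qnorm(1 - (1 - level) / 2),
    student_t = {
      if (n < 2) stop("student_t requires n >= 2")
      stats::qt(1 - (1 - level) / 2, df = n - 1)
    })
  c(ci_low = mean - q * sem, ci_high = mean + q * sem)
}

#' Summarize one group of measurements
#'
#' Mean, SEM (sample SD with the n - 1 denominator divided by sqrt(n)), and
#' confidence interval per [confidenceInterval()].
#'
#' @param values numeric vector (n >= 1).
#' @param level confidence level; default 0.95.
#' @param method CI method, `"normal_z"` (default) or `"student_t"`.
#' @param label group label carried into the result.
#' @return A [GroupSummary-class].
#' @examples
#' summarizeGroup(c(2, 4))  # mean 3, sem 1
#' @export
summarizeGroup <- function(values, level = 0.95,
                           method = c("normal_z", "student_t"), label = "") {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) stop("cannot summarize an empty group")
  m <- mean(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  ci <- if (method == "student_t" && n < 2) c(m, m)
        else confidenceInterval(m, sem, n, level, method)
  new("GroupSummary", mean = m, sem = sem, n = as.integer(n),
      ci_low = unname(ci[1]), ci_high = unname(ci[2]), ci_method = method,
      level = level, label = label)
}

#' Normality-routed two-group comparison
#'
#' Applies a Shapiro-Wilk normality test to each group; when both groups
#' pass at `alpha_normality` the groups are compared with an unpaired
#' two-tailed t-test (classical equal-variance by default; set
#' `var_equal = FALSE` for Welch), otherwise with a two-sided Mann-Whitney
#' test (exact distribution when the combined n is at most 20 and the data
#' are tie-free; normal approximation with continuity correction otherwise).
#' A group with zero variance cannot be tested for normality and routes the
#' comparison to Mann-Whitney.
#'
#' @param a,b numeric vectors, each with n >= 3.
#' @param alpha_normality significance level of the normality gate;
#'   default 0.05.
#' @param var_equal logical; classical equal-variance t-test (TRUE, default)
#'   or Welch.
#' @return A [TestResult-class] recording the statistic, the two-sided
#'   p-value, which test was used, and the per-group normality p-values.
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(10, 100, 15), rnorm(12, 84, 15))
#' @export
compareGroups <- function(a, b, alpha_normality = 0.05, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  shap <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- shap(a); pb <- shap(b)
  if (pa > alpha_normality && pb > alpha_normality) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- new("TestResult", statistic = unname(tt$statistic),
               p_value = tt$p.value, test_used = "unpaired_t",
               normality_p_a = pa, normality_p_b = pb,
               n_a = length(a), n_b = length(b), exact = NA)
  } else {
    exact <- (length(a) + length(b)) <= 20
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    # R silently falls back to the corrected normal approximation on ties
    used_exact <- exact && !any(duplicated(c(a, b)))
    res <- new("TestResult", statistic = unname(wt$statistic),
               p_value = wt$p.value, test_used = "mann_whitney",
               normality_p_a = pa, normality_p_b = pb,
               n_a = length(a), n_b = length(b), exact = used_exact)
  }
  res
}
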