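# Brain-age-gap statistics: gap computation and between-group comparison,
# from raw gaps or from printed summary statistics (n, mean, sd). The group
# test is the classic pooled-variance (Student) two-sample t-test.

#' Brain age gap
#'
#' `gap = predicted - age`; positive values indicate an older-appearing
#' brain (accelerated aging), negative values a younger-appearing one.
#'
#' @param predicted predicted brain age(s), years.
#' @param age chronological age(s), years.
#' @return gap(s) in years.
#' @export
brain_age_gap <- function(predicted, age) {
  if (any(!is.finite(predicted)) || any(!is.finite(age))) {
    stopf("inputs must be finite")
  }
  predicted - age
}

#' Group summary of brain-age gaps
#'
#' Container for printed summary statistics, as reported in clinical tables.
#'
#' @param n group size (>= 2).
#' @param mean_gap mean gap in years.
#' @param sd_gap standard deviation of the gap (>= 0).
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(n, mean_gap, sd_gap) {
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  if (sd_gap < 0) stopf("sd_gap must be >= 0")
  structure(list(n = as.integer(n), mean_gap = mean_gap, sd_gap = sd_gap),
            class = "group_summary")
}

gap_comparison <- function(t, df, mean_difference) {
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_difference = mean_difference),
            class = "gap_comparison")
}

#' @export
print.gap_comparison <- function(x, ...) {
  cat(sprintf("two-sample t = %.3f, df = %g, p = %.4g (mean difference %.3f years)\n",
              x$t, x$df, x$p, x$mean_difference))
  invisible(x)
}

#' Compare brain-age gaps between two groups (raw data)
#'
#' Independent two-sample pooled-variance t-test with
#' `df = n_a + n_b - 2` and a two-tailed p-value.
#'
#' @param gaps_a,gaps_b gap vectors (years), each of length >= 2.
#' @return an object of class `gap_comparison` (`t`, `df`, `p`,
#'   `mean_difference` = mean(a) - mean(b)).
#' @export
compare_groups <- function(gaps_a, gaps_b) {
  if (length(gaps_a) < 2L || length(gaps_b) < 2L) {
    stopf("each group needs at least 2 observations")
  }
  compare_groups_from_summary(
    group_summary(length(gaps_a), mean(gaps_a), stats::sd(gaps_a)),
    group_summary(length(gaps_b), mean(gaps_b), stats::sd(gaps_b))
  )
}

#' Compare brain-age gaps between two groups (summary statistics)
#'
#' Pooled-variance t computed directly from `(n, mean, sd)` pairs; agrees
#' with [compare_groups()] exactly when the summaries are unrounded.
#'
#' @param a,b [group_summary()] objects.
#' @return an object of class `gap_comparison`.
#' @examples
#' compare_groups_from_summary(group_summary(208, 0.413, 3.515),
#'                             group_summary(172, 1.393, 3.606))
#' @export
compare_groups_from_summary <- function(a, b) {
  if (!inherits(a, "group_summary") || !inherits(b, "group_summary")) {
    stopf("a and b must be group_summary objects")
  }
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd_gap^2 + (b$n - 1) * b$sd_gap^2) / df
  if (sp2 == 0) {
    if (a$mean_gap == b$mean_gap) return(gap_comparison(0, df, 0))
    stopf("zero pooled variance with unequal means: t undefined")
  }
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  gap_comparison((a$mean_gap - b$mean_gap) / se, df, a$mean_gap - b$mean_gap)
}
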