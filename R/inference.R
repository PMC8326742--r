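new_comparison <- function(statistic_name, estimate_A, estimate_B,
                           statistic, p_value, ci_95 = c(NA_real_, NA_real_),
                           df = NA_real_, note = NULL) {
  structure(list(statistic_name = statistic_name,
                 estimate_A = estimate_A, estimate_B = estimate_B,
                 difference = estimate_A - estimate_B,
                 statistic = statistic, df = df, p_value = p_value,
                 ci_95 = ci_95, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: A = %.3f, B = %.3f, difference = %.3f\n",
              x$statistic_name, x$estimate_A, x$estimate_B, x$difference))
  cat(sprintf("  statistic = %.4f%s, p = %.4g", x$statistic,
              if (!is.na(x$df)) sprintf(" (df %.2f)", x$df) else "", x$p_value))
  if (!any(is.na(x$ci_95))) cat(sprintf(", 95%% CI (%.3f, %.3f)", x$ci_95[1], x$ci_95[2]))
  cat("\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Two-sample t test from summary statistics
#'
#' Welch's unequal-variance t by default (Satterthwaite degrees of
#' freedom); `pooled = TRUE` gives the classical equal-variance test.
#'
#' @param mean_A,sd_A,n_A,mean_B,sd_B,n_B group summaries; n >= 2 each.
#' @param pooled use the pooled-variance statistic.
#' @return a `group_comparison` with the statistic, df, two-sided p and a
#'   95% CI for the mean difference.
#' @export
#' @examples
#' welch_t_test(10, 2, 100, 8, 2, 100)
welch_t_test <- function(mean_A, sd_A, n_A, mean_B, sd_B, n_B, pooled = FALSE) {
  if (n_A < 2 || n_B < 2) stopf("need n >= 2 in each group")
  if (sd_A < 0 || sd_B < 0) stopf("standard deviations must be non-negative")
  if (sd_A == 0 && sd_B == 0) stopf("both standard deviations are zero: statistic undefined")
  if (pooled) {
    sp2 <- ((n_A - 1) * sd_A^2 + (n_B - 1) * sd_B^2) / (n_A + n_B - 2)
    se <- sqrt(sp2 * (1 / n_A + 1 / n_B))
    df <- n_A + n_B - 2
  } else {
    vA <- sd_A^2 / n_A; vB <- sd_B^2 / n_B
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (n_A - 1) + vB^2 / (n_B - 1))
  }
  t <- (mean_A - mean_B) / se
  p <- 2 * stats::pt(-abs(t), df)
  half <- stats::qt(0.975, df) * se
  new_comparison(if (pooled) "pooled t-test" else "Welch t-test",
                 mean_A, mean_B, t, p,
                 ci_95 = c(mean_A - mean_B - half, mean_A - mean_B + half),
                 df = df)
}

#' Z test for a difference in life expectancies
#'
#' `z = (e_A - e_B) / sqrt(var_A + var_B)` with a two-sided normal p,
#' variances from [le_variance()].
#'
#' @param e_A,e_B life expectancies (years).
#' @param var_A,var_B their variances; non-negative, not both zero.
#' @return a `group_comparison`.
#' @export
#' @examples
#' le_difference_z_test(70.7, 0.004, 67.6, 0.005)
le_difference_z_test <- function(e_A, var_A, e_B, var_B) {
  if (var_A < 0 || var_B < 0) stopf("variances must be non-negative")
  if (var_A + var_B == 0) stopf("both variances are zero: statistic undefined")
  se <- sqrt(var_A + var_B)
  z <- (e_A - e_B) / se
  half <- stats::qnorm(0.975) * se
  new_comparison("life-expectancy z-test", e_A, e_B, z,
                 2 * stats::pnorm(-abs(z)),
                 ci_95 = c(e_A - e_B - half, e_A - e_B + half))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic on an r x c count table with
#' (r - 1)(c - 1) degrees of freedom; a warning is attached when any
#' expected cell count falls below 5.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return a `group_comparison`; `estimate_A`/`estimate_B` are the first
#'   two row proportions of the first column (NA for tables wider than
#'   needed for that summary).
#' @export
#' @examples
#' chi_square_test(matrix(c(10, 20, 20, 10), 2))
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  note <- if (any(res$expected < 5)) "expected cell count below 5" else NULL
  pa <- table[1, 1] / sum(table[1, ])
  pb <- if (nrow(table) >= 2) table[2, 1] / sum(table[2, ]) else NA_real_
  new_comparison("chi-square test", pa, pb,
                 unname(res$statistic), res$p.value,
                 df = unname(res$parameter), note = note)
}

#' Required sample size for a prevalence estimate
#'
#' \deqn{n = \frac{Z^2 p (1-p)}{e^2} \times DEff \times \text{adjustment}}
#' rounded up. The non-response adjustment has two conventions:
#' `inflate_multiply` scales by (1 + NR) and `inflate_divide` by
#' 1 / (1 - NR).
#'
#' @param Z standard-normal quantile (1.96 for 95% confidence).
#' @param p anticipated prevalence, in (0, 1).
#' @param e margin of error (fraction), positive.
#' @param DEff design effect, >= 1.
#' @param NR non-response rate, in \[0, 1).
#' @param mode `"inflate_divide"` (default) or `"inflate_multiply"`.
#' @return integer sample size; attribute `mode` records the adjustment.
#' @export
#' @examples
#' required_sample_size(1.96, 0.5, 0.05, DEff = 1, NR = 0)      # 385
#' required_sample_size(1.96, 0.084, 0.05, DEff = 2, NR = 0.02) # 242
required_sample_size <- function(Z, p, e, DEff = 1, NR = 0,
                                 mode = c("inflate_divide", "inflate_multiply")) {
  mode <- match.arg(mode)
  if (p <= 0 || p >= 1) stopf("p must lie strictly in (0, 1)")
  if (e <= 0) stopf("margin of error must be positive")
  if (DEff < 1) stopf("design effect must be >= 1")
  if (NR < 0 || NR >= 1) stopf("non-response rate must lie in [0, 1)")
  base <- Z^2 * p * (1 - p) / e^2 * DEff
  n <- switch(mode,
              inflate_multiply = base * (1 + NR),
              inflate_divide = base / (1 - NR))
  structure(as.integer(ceiling(n)), mode = mode)
}
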