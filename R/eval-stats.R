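#' Squared correlation between observed and predicted values
#'
#' The performance metric used for every model comparison: squared
#' Pearson correlation.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 values).
#' @return A fraction in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 2,
              "`observed` and `predicted` must be equal-length vectors of >= 2 values")
  if (pop_sd(observed) == 0) abort("`observed` is constant; r-squared undefined")
  if (pop_sd(predicted) == 0) {
    warn("constant predictions; r-squared reported as 0")
    return(0)
  }
  cor(observed, predicted)^2
}

#' Express model performance relative to the additive baseline
#'
#' Standardises results across traits: each model's r-squared as a
#' fraction of the additive-baseline r-squared, and the
#' nonlinear-vs-linear gap as a percentage of the baseline,
#' `100 * (r2_nl - r2_lin) / r2_base`. A fraction below 1 means the
#' network lost to the additive baseline.
#'
#' @param r2_nl,r2_lin,r2_base r-squared of the nonlinear network, linear
#'   network and additive baseline (vectorised; `r2_base` must be > 0).
#' @return A tibble with `fraction_of_baseline_nl`,
#'   `fraction_of_baseline_lin` and `gap_percent`.
#' @export
relative_metrics <- function(r2_nl, r2_lin, r2_base) {
  if (any(r2_base <= 0)) abort("`r2_base` must be > 0 (baseline failed)")
  tibble::tibble(
    fraction_of_baseline_nl = r2_nl / r2_base,
    fraction_of_baseline_lin = r2_lin / r2_base,
    gap_percent = 100 * (r2_nl - r2_lin) / r2_base)
}

#' Paired t-test over replicate gaps
#'
#' Classical paired t-test on per-replicate differences, two-sided, with
#' `n - 1` degrees of freedom. Supply either the per-replicate differences
#' (e.g. baseline-standardised gaps, tested against zero) or the two
#' paired arms.
#'
#' @param x Per-replicate differences, or the first arm when `y` is given.
#' @param y Optional second arm; differences are `x - y`.
#' @return A `comparison_summary`: mean difference, t statistic, two-sided
#'   p, replicate count and the per-replicate differences.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  n <- length(d)
  assert_that(n >= 2, "paired t-test needs at least 2 pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(structure(list(mean_gap = 0, t_statistic = NA_real_, p_value = 1,
                            n = n, gaps = d),
                       class = "comparison_summary"))
    }
    abort("degenerate paired t-test: identical nonzero differences")
  }
  ht <- stats::t.test(d)
  structure(
    list(mean_gap = mean(d), t_statistic = unname(ht$statistic),
         p_value = ht$p.value, n = n, gaps = d),
    class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("<comparison_summary> mean difference %.3f over %d replicates (t = %s, p = %.3g)\n",
              x$mean_gap, x$n,
              if (is.na(x$t_statistic)) "NA" else sprintf("%.3f", x$t_statistic),
              x$p_value))
  invisible(x)
}

#' Quality-control filter for relative results
#'
#' Removes low-signal records: those whose relative metric deviates from
#' the collection mean by more than `outlier_percent` percent of that
#' mean's magnitude (the mean is computed once, before any removal), and
#' those where any of the three model p-values (linear, nonlinear,
#' baseline) is missing or fails nominal significance.
#'
#' @param results Tibble with a `metric` column and p-value columns
#'   `p_linear`, `p_nonlinear`, `p_baseline`.
#' @param outlier_percent Allowed deviation from the mean, in percent of
#'   the mean's magnitude (default 500).
#' @param alpha Nominal significance level for the three models (default
#'   0.05).
#' @return The filtered tibble.
#' @export
qc_filter <- function(results, outlier_percent = 500, alpha = 0.05) {
  if (nrow(results) == 0) return(results)
  req <- c("metric", "p_linear", "p_nonlinear", "p_baseline")
  missing_cols <- setdiff(req, names(results))
  if (length(missing_cols) > 0) {
    abort(sprintf("`results` lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  m <- mean(results$metric)
  within <- abs(results$metric - m) <= (outlier_percent / 100) * abs(m)
  sig <- !is.na(results$p_linear) & results$p_linear < alpha &
    !is.na(results$p_nonlinear) & results$p_nonlinear < alpha &
    !is.na(results$p_baseline) & results$p_baseline < alpha
  results[within & sig, , drop = FALSE]
}
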