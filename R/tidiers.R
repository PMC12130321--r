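#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scenario result
#'
#' One row per replicate: the three test r-squared values, their
#' significance, and the baseline-standardised metrics.
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.scenario_result <- function(x, ...) x$replicates

#' @rdname tidy.scenario_result
#' @exportS3Method generics::glance
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$config$scenario,
    mitigation = x$config$mitigation,
    joint_tagging = x$config$joint_tagging,
    mean_gap_percent = x$comparison$mean_gap,
    t_statistic = x$comparison$t_statistic,
    p_value = x$comparison$p_value,
    n_replicates = x$comparison$n,
    mean_r2_nonlinear = mean(x$replicates$r2_nonlinear),
    mean_r2_linear = mean(x$replicates$r2_linear),
    mean_r2_baseline = mean(x$replicates$r2_baseline))
}

#' @rdname tidy.scenario_result
#' @exportS3Method generics::tidy
tidy.comparison_summary <- function(x, ...) {
  tibble::tibble(mean_gap = x$mean_gap, t_statistic = x$t_statistic,
                 p_value = x$p_value, n = x$n)
}

#' Tidy a trained network
#'
#' `tidy()` lists the layers with their shapes; `glance()` gives the
#' one-row training summary.
#'
#' @param x An `nn_network`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.nn_network <- function(x, ...) {
  dims <- c(x$input_dim, purrr::map_int(x$layers, ~ncol(.x$W)))
  tibble::tibble(
    layer = seq_along(x$layers),
    fan_in = dims[-length(dims)],
    fan_out = dims[-1],
    n_weights = purrr::map_int(x$layers, ~length(.x$W)),
    activation = if (x$nonlinear) "softplus" else "identity")
}

#' @rdname tidy.nn_network
#' @exportS3Method generics::glance
glance.nn_network <- function(x, ...) {
  tibble::tibble(
    nonlinear = x$nonlinear,
    n_parameters = n_parameters(x),
    trained = x$trained,
    best_epoch = x$best_epoch,
    epochs_run = length(x$val_trajectory),
    best_val_r2 = if (x$trained) max(x$val_trajectory) else NA_real_,
    learning_rate_used = x$lr_used,
    retrained = x$retrained)
}

#' Tidy a baseline regression model
#'
#' @param x A `baseline_model`.
#' @param ... Unused.
#' @return Coefficient tibble (`tidy`) or one-row fit summary (`glance`).
#' @exportS3Method generics::tidy
tidy.baseline_model <- function(x, ...) {
  coefs <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(coefs),
                 estimate = coefs[, 1], std_error = coefs[, 2],
                 statistic = coefs[, 3], p_value = coefs[, 4])
}

#' @rdname tidy.baseline_model
#' @exportS3Method generics::glance
glance.baseline_model <- function(x, ...) {
  if (x$family == "linear") {
    s <- summary(x$fit)
    tibble::tibble(family = x$family, r_squared = s$r.squared,
                   n_covariates_retained = length(x$retained),
                   n_obs = stats::nobs(x$fit))
  } else {
    tibble::tibble(family = x$family,
                   deviance_explained = 1 - x$fit$deviance / x$fit$null.deviance,
                   n_covariates_retained = length(x$retained),
                   n_obs = stats::nobs(x$fit))
  }
}

#' Plot per-replicate nonlinear-vs-linear gaps
#'
#' Dot plot of the baseline-standardised gap for each replicate with the
#' mean highlighted.
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_result <- function(object, ...) {
  dat <- object$replicates
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$replicate), y = .data$gap_percent)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$comparison$mean_gap, colour = "#d95f02") +
    ggplot2::labs(x = "replicate",
                  y = "nonlinear - linear gap (% of baseline r²)",
                  title = sprintf("%s scenario (mitigation: %s)",
                                  object$config$scenario, object$config$mitigation)) +
    ggplot2::theme_minimal()
}

#' Plot a training trajectory
#'
#' Validation r-squared per epoch, with the best epoch marked.
#'
#' @param object A trained `nn_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nn_network <- function(object, ...) {
  if (!object$trained) abort("network is untrained")
  dat <- tibble::tibble(epoch = seq_along(object$val_trajectory),
                        val_r2 = object$val_trajectory)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$val_r2)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "validation r²",
                  title = sprintf("%s network training",
                                  if (object$nonlinear) "nonlinear" else "linear")) +
    ggplot2::theme_minimal()
}

#' Plot fraction-of-baseline results
#'
#' Long-format comparison of linear and nonlinear network performance
#' expressed as a fraction of the additive baseline, one dot per
#' phenotype/scenario, mirroring the real-data reporting layout.
#'
#' @param results Tibble with columns `input_scenario` (or `scenario`),
#'   `fraction_of_baseline_nl` and `fraction_of_baseline_lin`.
#' @return A ggplot object.
#' @export
plot_fraction_of_baseline <- function(results) {
  key <- if ("input_scenario" %in% names(results)) "input_scenario" else "scenario"
  long <- tidyr::pivot_longer(results,
                              c("fraction_of_baseline_nl", "fraction_of_baseline_lin"),
                              names_to = "model", values_to = "fraction")
  long$model <- ifelse(grepl("_nl$", long$model), "nonlinear", "linear")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[key]], y = .data$fraction,
                                     colour = .data$model)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4), size = 2) +
    ggplot2::scale_colour_manual(values = c(linear = "#e6862c", nonlinear = "#2c7fb8")) +
    ggplot2::labs(y = "test r² as fraction of baseline", x = NULL) +
    ggplot2::theme_minimal()
}
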