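#' Density panels of replicate hazard-ratio estimates
#'
#' Draws the Gaussian-kernel density of the hazard-ratio estimates for each
#' coefficient, optionally overlaying several scenarios (e.g. weighted vs
#' unweighted fits) and the census reference values as dashed vertical lines.
#'
#' @param estimates A replicate tibble from [run_replications()], or a named
#'   list of them (names become the scenario legend).
#' @param reference Optional `svycox_fit` whose hazard ratios are drawn as
#'   dashed vertical reference lines.
#' @return A ggplot object, faceted by coefficient.
#' @export
plot_hr_density <- function(estimates, reference = NULL) {
  if (is.data.frame(estimates)) {
    tab <- dplyr::mutate(estimates, scenario = "estimates")
    one <- TRUE
  } else {
    tab <- dplyr::bind_rows(estimates, .id = "scenario")
    one <- FALSE
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$hr)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free") +
    ggplot2::labs(x = "hazard ratio", y = "density") +
    ggplot2::theme_minimal()
  p <- if (one) {
    p + ggplot2::geom_density()
  } else {
    p + ggplot2::geom_density(ggplot2::aes(colour = .data$scenario))
  }
  if (!is.null(reference)) {
    ref <- tibble::tibble(term = names(coef(reference)),
                          hr = exp(unname(coef(reference))))
    ref <- dplyr::semi_join(ref, tab, by = "term")
    p <- p + ggplot2::geom_vline(data = ref,
                                 ggplot2::aes(xintercept = .data$hr),
                                 linetype = "dashed")
  }
  p
}

#' Bar chart of a summary metric across scenarios
#'
#' Mirrors the study's overall-comparison displays: one bar per scenario and
#' coefficient for the average estimated variance, the empirical variance,
#' or the mean squared error.
#'
#' @param comparison A tibble from [compare_scenarios()] (or a summary tibble
#'   with a `scenario` column).
#' @param metric One of `"mse"`, `"avg_est_var"`, `"emp_var"`.
#' @return A ggplot object.
#' @export
plot_scenario_metric <- function(comparison,
                                 metric = c("mse", "avg_est_var", "emp_var")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$term, y = .data[[metric]],
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.svycox_fit <- function(object, ...) {
  td <- tidy(object)
  td$lo <- exp(td$estimate - 1.96 * td$robust_se)
  td$hi <- exp(td$estimate + 1.96 * td$robust_se)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "hazard ratio (95% CI, robust SE)", y = NULL) +
    ggplot2::theme_minimal()
}
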