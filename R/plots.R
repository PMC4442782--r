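# Residual-by-decile figures: one panel per family parameter, one line per
# estimator, averaged over replications. Figures are drawn from the
# `profiles` tibble a grid run already computed -- never by re-fitting.

#' Residual-by-decile figure for one family and sample size
#'
#' For each parameter value of the chosen family (one panel each), plots
#' the mean original-scale residual in each covariate decile, one line per
#' estimator. An unbiased estimator tracks zero; systematic curvature or
#' offset reveals bias in the mean predictions along the covariate.
#'
#' @param profiles A profiles tibble (from `run_grid()$profiles` or
#'   `profiles.csv`): columns `family`, `param`, `n`, `estimator`,
#'   `decile`, `mean_residual`.
#' @param family Generating family to display.
#' @param n Sample size to display.
#' @return A ggplot object (panels: one per parameter value).
#' @export
plot_residual_profiles <- function(profiles, family, n) {
  rows <- dplyr::filter(profiles, .data$family == !!family, .data$n == !!n)
  if (!nrow(rows)) {
    abort(sprintf("No profile rows for family %s at n = %d.", family, n),
          class = "costsim_domain_error")
  }
  missing <- dplyr::anti_join(
    dplyr::distinct(profiles[profiles$family == family, ], .data$param),
    dplyr::distinct(rows, .data$param),
    by = "param"
  )
  if (nrow(missing)) {
    warn(sprintf("Skipping parameter(s) without rows at n = %d: %s",
                 n, paste(missing$param, collapse = ", ")))
  }
  param_label <- if (family == "lognormal") "sigma^2" else "shape"
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$decile,
                                     y = .data$mean_residual,
                                     colour = .data$estimator)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~param, scales = "free_y",
                        labeller = ggplot2::labeller(
                          param = function(v) paste(param_label, "=", v))) +
    ggplot2::scale_x_continuous(breaks = 1:10, minor_breaks = NULL) +
    ggplot2::labs(
      title = sprintf("Mean residual across deciles of x (%s data, n = %d)",
                      family, n),
      x = "decile of x", y = "mean residual", colour = "estimator"
    ) +
    ggplot2::theme_bw()
}

#' Autoplot a simulation grid
#'
#' Convenience wrapper around [plot_residual_profiles()] for a
#' `cost_sim_table`.
#'
#' @param object A `cost_sim_table`.
#' @param family Generating family to display (default: first in the grid).
#' @param n Sample size to display (default: smallest in the grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_sim_table <- function(object, family = NULL, n = NULL, ...) {
  family <- family %||% object$profiles$family[1]
  n <- n %||% min(object$profiles$n)
  plot_residual_profiles(object$profiles, family, n)
}
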