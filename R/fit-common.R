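# Common contract for the four estimators. Every fitter takes a data frame
# with columns y (positive cost) and x (covariate) and returns a `cost_fit`
# holding, whatever the model, the slope estimate and original-scale mean
# predictions -- so the metrics layer never needs to know which model ran.

validate_cost_data <- function(data, require_positive_y = TRUE, min_n = 3L) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `y` and `x`.",
          class = "costsim_domain_error")
  }
  if (!all(c("y", "x") %in% names(data))) {
    abort("`data` must contain columns `y` and `x`.",
          class = "costsim_domain_error")
  }
  y <- data$y
  x <- data$x
  if (length(y) < min_n) {
    abort(sprintf("At least %d observations are required.", min_n),
          class = "costsim_domain_error")
  }
  if (anyNA(y) || anyNA(x) || !all(is.finite(y)) || !all(is.finite(x))) {
    abort("`y` and `x` must be finite and non-missing.",
          class = "costsim_domain_error")
  }
  if (require_positive_y && any(y <= 0)) {
    abort("All costs `y` must be strictly positive.",
          class = "costsim_domain_error")
  }
  list(y = as.numeric(y), x = as.numeric(x), n = length(y))
}

new_cost_fit <- function(estimator, beta0_hat, beta1_hat, aux, y, x, yhat,
                         loglik, aic, converged, flags = character()) {
  structure(
    list(
      estimator = estimator,
      beta0_hat = beta0_hat,
      beta1_hat = beta1_hat,
      aux = aux,
      fitted = tibble::tibble(y = y, x = x, .fitted = yhat,
                              .resid = y - yhat),
      loglik = loglik,
      aic = aic,
      converged = converged,
      flags = flags
    ),
    class = "cost_fit"
  )
}

#' @export
print.cost_fit <- function(x, ...) {
  cat(sprintf("<cost_fit: %s>\n", x$estimator))
  cat(sprintf("  beta0_hat = %s, beta1_hat = %.6f\n",
              if (x$estimator == "cox_ph") "(undefined)" else
                sprintf("%.6f", x$beta0_hat),
              x$beta1_hat))
  cat(sprintf("  n = %d, logLik = %s, AIC = %s, converged = %s\n",
              nrow(x$fitted),
              format_or_na(x$loglik), format_or_na(x$aic), x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

format_or_na <- function(v) {
  if (is.null(v) || is.na(v)) "NA" else sprintf("%.3f", v)
}

#' Tidy a cost-model fit
#'
#' @param x A `cost_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`). The
#'   Cox model contributes only the slope, since its intercept is absorbed
#'   into the nonparametric baseline hazard.
#' @export
tidy.cost_fit <- function(x, ...) {
  if (x$estimator == "cox_ph") {
    tibble::tibble(term = "x", estimate = x$beta1_hat)
  } else {
    tibble::tibble(term = c("(Intercept)", "x"),
                   estimate = c(x$beta0_hat, x$beta1_hat))
  }
}

#' One-row summary of a cost-model fit
#'
#' @param x A `cost_fit`.
#' @param ... Unused.
#' @return A one-row tibble: estimator, slope, auxiliary shape/variance
#'   parameter (where the model has one), log-likelihood, AIC, convergence.
#' @export
glance.cost_fit <- function(x, ...) {
  aux_value <- switch(x$estimator,
    ols_log = x$aux$sigma2,
    gamma_glm = x$aux$dispersion,
    weibull_reg = x$aux$shape,
    cox_ph = NA_real_
  )
  tibble::tibble(
    estimator = x$estimator,
    beta1_hat = x$beta1_hat,
    aux_parameter = aux_value,
    logLik = x$loglik %||% NA_real_,
    AIC = x$aic %||% NA_real_,
    nobs = nrow(x$fitted),
    converged = x$converged
  )
}

#' Per-observation results of a cost-model fit
#'
#' @param x A `cost_fit`.
#' @param ... Unused.
#' @return The fitted tibble: `y`, `x`, `.fitted` (original-scale mean
#'   prediction) and `.resid`.
#' @export
augment.cost_fit <- function(x, ...) x$fitted

#' Model-based conditional variance of cost at the fitted values
#'
#' Used as the denominator weights of the decile goodness-of-fit statistic
#' in [hl_test()]. Each estimator implies its own mean-variance
#' relationship: log-normal `yhat^2 * (exp(s2) - 1)`; gamma
#' `dispersion * yhat^2`; Weibull `b^2 * (gamma(1 + 2/a) - gamma(1 + 1/a)^2)`
#' at the fitted scale `b`; Cox the variance implied by the fitted survival
#' step function (second moment by exact integration of `2 t S(t|x)`).
#'
#' @param fit A `cost_fit`.
#' @return A numeric vector of conditional variances, one per observation.
#' @export
model_variance <- function(fit) {
  stopifnot(inherits(fit, "cost_fit"))
  yhat <- fit$fitted$.fitted
  switch(fit$estimator,
    ols_log = {
      s2 <- fit$aux$sigma2
      mu <- exp(fit$beta0_hat + fit$beta1_hat * fit$fitted$x + s2 / 2)
      pmax(mu^2 * (exp(s2) - 1), .Machine$double.eps)
    },
    gamma_glm = pmax(fit$aux$dispersion * yhat^2, .Machine$double.eps),
    weibull_reg = {
      a <- fit$aux$shape
      b <- exp(fit$beta0_hat + fit$beta1_hat * fit$fitted$x)
      pmax(b^2 * (gamma(1 + 2 / a) - gamma(1 + 1 / a)^2),
           .Machine$double.eps)
    },
    cox_ph = pmax(fit$aux$second_moment - yhat^2, .Machine$double.eps)
  )
}
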