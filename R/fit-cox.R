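#' Cox proportional hazards fit with restricted-mean cost predictions
#'
#' Treats each cost as a fully observed "event time" and fits
#' `h(t|x) = h0(t) exp(beta1 * x)` by partial likelihood with Breslow tie
#' handling. The baseline cumulative hazard `H0` is the Breslow estimator;
#' the fitted survival is `S(t|x) = exp(-H0(t) exp(beta1 * x))`, and the
#' mean-cost prediction is the restricted mean
#' `integral of S(t|x) dt from 0 to max(y)`, evaluated exactly as the area
#' under the survival step function (no tail extrapolation beyond the
#' largest observed cost). The model has no intercept -- the baseline
#' absorbs it -- so `beta0_hat` is stored as 0 and flagged.
#'
#' With a constant covariate the partial likelihood carries no information:
#' the fit returns `beta1_hat = 0` (flagged `"constant_x"`) and predicts the
#' sample mean of `y` for every observation, the restricted mean of the
#' no-covariate survival estimate on uncensored data.
#'
#' @inheritParams fit_ols_log
#' @return A `cost_fit` with `aux$basehaz` (tibble `time`, `hazard`),
#'   `aux$coxph` (the underlying [survival::coxph()] fit, when defined) and
#'   `aux$second_moment` (per-observation `E(y^2|x)` implied by the fitted
#'   survival, used for variance weights). `loglik`/`aic` are
#'   partial-likelihood quantities with one parameter.
#' @examples
#' d <- generate_costs(dgp_spec("weibull", 5, n = 200), seed = 11)
#' fit <- fit_cox_ph(d)
#' tidy(fit)
#' @export
fit_cox_ph <- function(data) {
  d <- validate_cost_data(data, require_positive_y = TRUE)
  if (var(d$x) == 0) {
    n <- d$n
    m <- mean(d$y)
    return(new_cost_fit(
      estimator = "cox_ph",
      beta0_hat = 0, beta1_hat = 0,
      aux = list(basehaz = NULL, coxph = NULL,
                 second_moment = rep(mean(d$y^2), n),
                 beta0_defined = FALSE),
      y = d$y, x = d$x, yhat = rep(m, n),
      loglik = NA_real_, aic = NA_real_,
      converged = TRUE,
      flags = c("constant_x", "beta0_undefined")
    ))
  }
  df <- data.frame(y = d$y, x = d$x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(y, rep(1, d$n)) ~ x, data = df,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta1 <- coef(fit)[[1]]
  bh <- survival::basehaz(fit, centered = FALSE)
  pred <- cox_restricted_moments(bh$time, bh$hazard, exp(beta1 * d$x))
  ll <- fit$loglik[2]
  new_cost_fit(
    estimator = "cox_ph",
    beta0_hat = 0, beta1_hat = beta1,
    aux = list(basehaz = tibble::tibble(time = bh$time, hazard = bh$hazard),
               coxph = fit,
               second_moment = pred$second_moment,
               beta0_defined = FALSE),
    y = d$y, x = d$x, yhat = pred$mean,
    loglik = ll, aic = -2 * ll + 2 * 1,
    converged = converged,
    flags = "beta0_undefined"
  )
}

# Restricted mean and second moment under S(t|x) = exp(-H0(t) * r), where
# H0 is a right-continuous step function with values `hazard` at the sorted
# event times `time` (H0 = 0 before the first event), truncated at max(time).
# mean   = t1 + sum_j (t_{j+1} - t_j) * S(t_j | x)
# E(t^2) = t1^2 + sum_j (t_{j+1}^2 - t_j^2) * S(t_j | x)
cox_restricted_moments <- function(time, hazard, risk) {
  k <- length(time)
  if (k == 1L) {
    return(list(mean = rep(time, length(risk)),
                second_moment = rep(time^2, length(risk))))
  }
  surv <- exp(-outer(hazard[-k], risk))      # (k-1) x n
  w1 <- diff(time)
  w2 <- diff(time^2)
  list(
    mean = time[1] + colSums(w1 * surv),
    second_moment = time[1]^2 + colSums(w2 * surv)
  )
}

#' Proportional-hazards diagnostic for a Cox fit
#'
#' Correlation test of scaled Schoenfeld residuals against a transform of
#' the event time ([survival::cox.zph()], Kaplan-Meier transform by
#' default). A small p-value flags a violation of the proportional-hazards
#' assumption.
#'
#' @param fit A `cost_fit` produced by [fit_cox_ph()].
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return The p-value of the covariate's PH test, or `NA_real_` (with a
#'   classed warning) when the test is undefined: constant covariate, or
#'   fewer than 3 distinct event times.
#' @examples
#' d <- generate_costs(dgp_spec("weibull", 1, n = 100), seed = 2)
#' ph_diagnostic(fit_cox_ph(d))
#' @export
ph_diagnostic <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cost_fit"))
  if (fit$estimator != "cox_ph") {
    abort("`ph_diagnostic()` requires a `cox_ph` fit.",
          class = "costsim_domain_error")
  }
  if (is.null(fit$aux$coxph) ||
      length(unique(fit$fitted$y)) < 3L) {
    warn("Proportional-hazards test is undefined for this fit.",
         class = "costsim_ph_undefined")
    return(NA_real_)
  }
  zph <- survival::cox.zph(fit$aux$coxph, transform = transform)
  unname(zph$table[1, "p"])
}
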