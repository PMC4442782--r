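#' Specify a skewed cost data-generating process
#'
#' A DGP specification fixes one simulation scenario: the generating family,
#' its skewness-controlling parameter, the covariate slope and the sample
#' size. The intercept `beta0` is not free: it is solved so that the marginal
#' population mean of cost equals 1 (with `x ~ Uniform(0, 1)`), which makes
#' bias metrics directly comparable across families and parameters.
#'
#' The three families and the meaning of `param`:
#' \describe{
#'   \item{`lognormal`}{`y = exp(beta0 + beta1 * x + e)`, `e ~ N(0, param)`;
#'     `param` is the log-scale variance `sigma^2`.}
#'   \item{`gamma`}{`y ~ Gamma(shape = param, scale = b)` with
#'     `b = exp(beta0 + beta1 * x)`; conditional mean `param * b`.}
#'   \item{`weibull`}{`y ~ Weibull(shape = param, scale = b)` with
#'     `b = exp(beta0 + beta1 * x)`; conditional mean
#'     `b * gamma(1 + 1/param)`. This family has exactly proportional
#'     hazards in `x`.}
#' }
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param param Positive scalar: log-scale variance for `lognormal`,
#'   shape for `gamma`/`weibull`.
#' @param n Sample size per replication (at least 3).
#' @param beta1 Covariate slope on the log scale (default 1).
#' @return An object of class `dgp_spec`: a list with `family`, `param`,
#'   `beta1`, `beta0` (solved) and `n`.
#' @examples
#' spec <- dgp_spec("gamma", param = 4, n = 100)
#' spec$beta0
#' @export
dgp_spec <- function(family = c("lognormal", "gamma", "weibull"),
                     param, n, beta1 = 1) {
  family <- match.arg(family)
  check_positive_scalar(param, "param")
  if (!is.numeric(beta1) || length(beta1) != 1L || !is.finite(beta1)) {
    abort("`beta1` must be a finite numeric scalar.", class = "costsim_domain_error")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 || n != trunc(n)) {
    abort("`n` must be an integer sample size of at least 3.",
          class = "costsim_domain_error")
  }
  beta0 <- solve_intercept(family, param, beta1)
  structure(
    list(family = family, param = param, beta1 = beta1, beta0 = beta0,
         n = as.integer(n)),
    class = "dgp_spec"
  )
}

#' @export
print.dgp_spec <- function(x, ...) {
  param_label <- if (x$family == "lognormal") "sigma^2" else "shape"
  cat(sprintf("<dgp_spec> %s (%s = %g), beta0 = %.6f, beta1 = %g, n = %d\n",
              x$family, param_label, x$param, x$beta0, x$beta1, x$n))
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name),
          class = "costsim_domain_error")
  }
  invisible(x)
}

#' Mean of exp(beta1 * x) for x ~ Uniform(0, 1)
#'
#' `(exp(b) - 1) / b`, with the limit 1 at `b = 0`. This is the factor by
#' which averaging the log-linear predictor over the uniform covariate
#' inflates the marginal mean.
#' @noRd
uniform_exp_mean <- function(b) {
  if (abs(b) < 1e-8) 1 + b / 2 else (exp(b) - 1) / b
}

#' Solve the intercept for a mean-standardized cost process
#'
#' Returns the intercept `beta0` such that the marginal mean of cost,
#' averaged over `x ~ Uniform(0, 1)`, equals 1. With conditional mean
#' `A * exp(beta0 + beta1 * x)` (where `A` is `exp(sigma^2 / 2)`, the gamma
#' shape, or `gamma(1 + 1/shape)` for Weibull), the closed form is
#' `beta0 = -log(A * (exp(beta1) - 1) / beta1)`.
#'
#' @inheritParams dgp_spec
#' @param method `"closed"` uses the closed form above; `"quadrature"`
#'   solves the same standardization by numerical integration over `x`
#'   (kept as an internal cross-check, and usable for exotic slopes).
#' @return The scalar intercept `beta0`.
#' @examples
#' solve_intercept("lognormal", 0.5, beta1 = 1)  # about -0.7913
#' @export
solve_intercept <- function(family = c("lognormal", "gamma", "weibull"),
                            param, beta1 = 1,
                            method = c("closed", "quadrature")) {
  family <- match.arg(family)
  method <- match.arg(method)
  check_positive_scalar(param, "param")
  if (!is.numeric(beta1) || length(beta1) != 1L || !is.finite(beta1)) {
    abort("`beta1` must be a finite numeric scalar.", class = "costsim_domain_error")
  }
  amp <- switch(family,
    lognormal = exp(param / 2),
    gamma = param,
    weibull = gamma(1 + 1 / param)
  )
  if (method == "closed") {
    -log(amp * uniform_exp_mean(beta1))
  } else {
    mean_factor <- integrate(function(x) exp(beta1 * x), 0, 1,
                             rel.tol = 1e-12)$value
    -log(amp * mean_factor)
  }
}

#' Generate one replication of skewed cost data
#'
#' Draws `n` covariate values `x ~ Uniform(0, 1)` and strictly positive
#' costs `y` from the spec's family. The draw is fully reproducible: the
#' same `(spec, seed)` pair gives the identical sample.
#'
#' @param spec A [dgp_spec()].
#' @param seed Integer seed for this replication.
#' @return A tibble with columns `y` and `x` (one row per observation),
#'   carrying the spec and seed as attributes `"spec"` and `"seed"`.
#' @examples
#' d <- generate_costs(dgp_spec("lognormal", 1, n = 50), seed = 7)
#' mean(d$y)
#' @export
generate_costs <- function(spec, seed) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "costsim_domain_error")
  }
  set.seed(as.integer(seed))
  raw <- generate_costs_raw(spec)
  out <- tibble::tibble(y = raw$y, x = raw$x)
  attr(out, "spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  out
}

# Draws from the current RNG state; no seeding, no tibble overhead.
# Used by the simulation engine's inner loop.
generate_costs_raw <- function(spec) {
  x <- runif(spec$n)
  lp <- spec$beta0 + spec$beta1 * x
  y <- switch(spec$family,
    lognormal = exp(lp + rnorm(spec$n, 0, sqrt(spec$param))),
    gamma = rgamma(spec$n, shape = spec$param, scale = exp(lp)),
    weibull = rweibull(spec$n, shape = spec$param, scale = exp(lp))
  )
  list(x = x, y = y)
}

#' Closed-form moments of a mean-standardized cost process
#'
#' Marginal mean (1 by construction), marginal standard deviation, and the
#' conditional-on-`x` skewness of the generating family. The marginal second
#' moment accounts for the uniform covariate mixture:
#' `E(y^2) = C * K` with `C = [(exp(2 b) - 1) / (2 b)] * [b / (exp(b) - 1)]^2`
#' (`b = beta1`, limit 1 at `b = 0`) and `K` the family's ratio
#' `E(y^2|x) / E(y|x)^2`: `exp(sigma^2)` (log-normal), `(a + 1)/a` (gamma),
#' `gamma(1 + 2/a) / gamma(1 + 1/a)^2` (Weibull).
#'
#' Conditional skewness is the standardized third central moment at fixed
#' `x`: `(exp(s2) + 2) * sqrt(exp(s2) - 1)` for the log-normal,
#' `2 / sqrt(a)` for the gamma, and the standardized Weibull third moment
#' for the Weibull family. It does not depend on `x` because `x` only moves
#' the scale.
#'
#' @param spec A [dgp_spec()].
#' @return A one-row tibble: `family`, `param`, `beta1`, `mean`, `sd`,
#'   `conditional_skewness`.
#' @examples
#' theoretical_moments(dgp_spec("lognormal", 1, n = 100))$sd  # about 1.393
#' @export
theoretical_moments <- function(spec) {
  stopifnot(inherits(spec, "dgp_spec"))
  b <- spec$beta1
  mix <- if (abs(b) < 1e-8) {
    1
  } else {
    ((exp(2 * b) - 1) / (2 * b)) * (b / (exp(b) - 1))^2
  }
  a <- spec$param
  k <- switch(spec$family,
    lognormal = exp(a),
    gamma = (a + 1) / a,
    weibull = gamma(1 + 2 / a) / gamma(1 + 1 / a)^2
  )
  m2 <- mix * k
  skew <- switch(spec$family,
    lognormal = (exp(a) + 2) * sqrt(exp(a) - 1),
    gamma = 2 / sqrt(a),
    weibull = weibull_skewness(a)
  )
  tibble::tibble(
    family = spec$family, param = a, beta1 = b,
    mean = 1, sd = sqrt(m2 - 1), conditional_skewness = skew
  )
}

# Standardized skewness of Weibull(shape = a): scale-free, so computed at
# scale 1. (The unnormalized third-central-moment expression sometimes seen
# in print is the numerator below at b = 1.)
weibull_skewness <- function(a) {
  g1 <- gamma(1 + 1 / a)
  g2 <- gamma(1 + 2 / a)
  g3 <- gamma(1 + 3 / a)
  mu3 <- g3 - 3 * g1 * g2 + 2 * g1^3
  sig2 <- g2 - g1^2
  mu3 / sig2^1.5
}

#' Population Cox coefficient implied by a DGP
#'
#' The Weibull family with log-linear scale has hazard
#' `h(t | x) = a * t^(a-1) * exp(-a * (beta0 + beta1 * x))`, so the
#' proportional-hazards log hazard ratio per unit of `x` is exactly
#' `-a * beta1`. The log-normal and gamma families do not satisfy
#' proportional hazards, so no population Cox coefficient is defined for
#' them: the function returns `NA` with a classed warning.
#'
#' @param spec A [dgp_spec()].
#' @return `-param * beta1` for the Weibull family; `NA_real_` (with a
#'   warning of class `costsim_no_ph_truth`) otherwise.
#' @examples
#' true_cox_coefficient(dgp_spec("weibull", 5, n = 100))  # -5
#' @export
true_cox_coefficient <- function(spec) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (spec$family != "weibull") {
    warn(sprintf(
      "The population Cox coefficient is not defined under the %s family (no proportional hazards).",
      spec$family
    ), class = "costsim_no_ph_truth")
    return(NA_real_)
  }
  -spec$param * spec$beta1
}
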