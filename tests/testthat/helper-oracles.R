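# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain algebra, brute-force search, direct integration.

# Least squares of log(y) on (1, x) via the normal equations.
ols_log_oracle <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% log(y))
  res <- log(y) - X %*% beta
  list(beta0 = beta[1], beta1 = beta[2],
       sigma2 = sum(res^2) / (n - 2),
       phi = mean(exp(res)),
       lp = as.numeric(X %*% beta))
}

# Breslow-ties Cox partial log-likelihood for fully observed event times.
cox_partial_loglik <- function(beta, y, x) {
  ord <- order(y)
  y <- y[ord]; x <- x[ord]
  n <- length(y)
  ll <- 0
  for (i in seq_len(n)) {
    at_risk <- y >= y[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Two-stage brute-force grid maximization of the partial likelihood.
cox_grid_oracle <- function(y, x, lo = -8, hi = 8) {
  g1 <- seq(lo, hi, by = 0.01)
  v1 <- vapply(g1, cox_partial_loglik, numeric(1), y = y, x = x)
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  v2 <- vapply(g2, cox_partial_loglik, numeric(1), y = y, x = x)
  g2[which.max(v2)]
}

# Breslow baseline cumulative hazard and restricted-mean predictions,
# written from the definitions (distinct event times, no ties assumed).
cox_restricted_mean_oracle <- function(y, x, beta) {
  times <- sort(unique(y))
  risk <- exp(beta * x)
  H <- cumsum(vapply(times, function(t) {
    sum(y == t) / sum(risk[y >= t])
  }, numeric(1)))
  vapply(seq_along(x), function(i) {
    s <- exp(-H * risk[i])
    # area under the right-continuous step survival on [0, max(y)]
    times[1] + sum(diff(times) * s[-length(s)])
  }, numeric(1))
}

# Marginal second moment of the standardized DGP by direct integration of
# the family's conditional second moment over x ~ U(0,1).
marginal_m2_oracle <- function(family, param, beta1 = 1) {
  b0 <- solve_intercept(family, param, beta1)
  cond_m2 <- switch(family,
    lognormal = function(x) exp(2 * (b0 + beta1 * x) + 2 * param),
    gamma = function(x) param * (param + 1) * exp(2 * (b0 + beta1 * x)),
    weibull = function(x) gamma(1 + 2 / param) * exp(2 * (b0 + beta1 * x))
  )
  stats::integrate(cond_m2, 0, 1, rel.tol = 1e-12)$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
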