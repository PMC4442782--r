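test_that("solved intercepts standardize the population mean to 1", {
  # closed forms against Monte Carlo derived reference values (+/- 1e-3)
  expect_equal(solve_intercept("lognormal", 0.5, 1), -0.79132, tolerance = 2e-3)
  expect_equal(solve_intercept("gamma", 4, 1), -1.92770, tolerance = 2e-3)
  expect_equal(solve_intercept("weibull", 5, 1), -0.45597, tolerance = 2e-3)

  # degenerate limit: vanishing variance and slope force beta0 -> 0
  expect_equal(solve_intercept("lognormal", 1e-12, 0), 0, tolerance = 1e-9)

  # closed form and quadrature agree to numerical precision on the grid
  for (fam in c("lognormal", "gamma", "weibull")) {
    for (p in c(0.5, 1, 2, 5)) {
      for (b1 in c(-0.7, 0, 1, 2.3)) {
        expect_equal(
          solve_intercept(fam, p, b1),
          solve_intercept(fam, p, b1, method = "quadrature"),
          tolerance = 1e-10
        )
      }
    }
  }
})

test_that("intercept solving rejects invalid domains", {
  expect_error(solve_intercept("gamma", 0, 1), class = "costsim_domain_error")
  expect_error(solve_intercept("gamma", -1, 1), class = "costsim_domain_error")
  expect_error(solve_intercept("weibull", Inf, 1), class = "costsim_domain_error")
  expect_error(solve_intercept("lognormal", 1, NA_real_),
               class = "costsim_domain_error")
  expect_error(dgp_spec("gamma", 1, n = 2), class = "costsim_domain_error")
})

test_that("generated samples are reproducible, positive and mean-standardized", {
  spec <- dgp_spec("gamma", 0.5, n = 200)
  d1 <- generate_costs(spec, seed = 11)
  d2 <- generate_costs(spec, seed = 11)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$x, d2$x)
  d3 <- generate_costs(spec, seed = 12)
  expect_false(identical(d1$y, d3$y))

  for (fam in c("lognormal", "gamma", "weibull")) {
    spec <- dgp_spec(fam, 0.5, n = 2e5)
    d <- generate_costs(spec, seed = 21)
    expect_true(all(d$y > 0))
    expect_true(all(d$x >= 0 & d$x <= 1))
    expect_length(d$y, spec$n)
    se <- sd(d$y) / sqrt(spec$n)
    expect_lt(abs(mean(d$y) - 1), 4 * se)
  }

  # vanishing noise with zero slope collapses to y = 1
  d <- generate_costs(dgp_spec("lognormal", 1e-14, n = 50, beta1 = 0), seed = 1)
  expect_equal(d$y, rep(1, 50), tolerance = 1e-6)
})

test_that("gamma generation with shape 1 is the exponential special case", {
  spec <- dgp_spec("gamma", 1, n = 1e5, beta1 = 0)  # constant scale exp(b0) = 1
  d <- generate_costs(spec, seed = 5)
  ks <- stats::ks.test(d$y, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("closed-form moments match direct integration and known values", {
  expect_equal(theoretical_moments(dgp_spec("gamma", 4, n = 10))$conditional_skewness, 1)
  expect_equal(
    theoretical_moments(dgp_spec("lognormal", 1, n = 10))$conditional_skewness,
    6.1849, tolerance = 1e-4
  )
  for (fam in c("lognormal", "gamma", "weibull")) {
    for (p in c(0.5, 2)) {
      mom <- theoretical_moments(dgp_spec(fam, p, n = 10))
      expect_equal(mom$mean, 1)
      expect_equal(mom$sd, sqrt(marginal_m2_oracle(fam, p) - 1),
                   tolerance = 1e-8)
    }
  }
  # reference value for the log-normal variance-1 scenario
  expect_equal(theoretical_moments(dgp_spec("lognormal", 1, n = 10))$sd,
               1.3933, tolerance = 1e-4)
})

test_that("large-sample moments match the closed forms", {
  spec <- dgp_spec("weibull", 5, n = 5e5)
  d <- generate_costs(spec, seed = 31)
  mom <- theoretical_moments(spec)
  expect_equal(sd(d$y), mom$sd, tolerance = 0.01)
  # conditional skewness: compare within a thin slice of x
  idx <- abs(d$x - 0.5) < 0.01
  sl <- sample_moments(d$y[idx])
  expect_equal(sl$skewness, mom$conditional_skewness, tolerance = 0.15)
})

test_that("the population Cox coefficient is -shape * beta1, Weibull only", {
  expect_equal(true_cox_coefficient(dgp_spec("weibull", 1, n = 10)), -1)
  expect_equal(true_cox_coefficient(dgp_spec("weibull", 5, n = 10)), -5)
  expect_equal(true_cox_coefficient(dgp_spec("weibull", 2, n = 10, beta1 = 0)), 0)
  expect_warning(
    res <- true_cox_coefficient(dgp_spec("gamma", 1, n = 10)),
    class = "costsim_no_ph_truth"
  )
  expect_true(is.na(res))

  # large-n Cox fit recovers it under the Weibull family
  d <- generate_costs(dgp_spec("weibull", 1, n = 3000), seed = 41)
  fit <- fit_cox_ph(d)
  expect_equal(fit$beta1_hat, -1, tolerance = 0.15)
})
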