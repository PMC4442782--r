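test_that("prediction-error statistics follow their definitions", {
  expect_equal(mpe(c(1, 2), c(1, 2)), 0)
  expect_equal(mpe(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_equal(mpe(c(1, 3), c(2, 4)), -1)
  expect_equal(mape(c(1, 2), c(1, 2)), 0)
  expect_equal(mape(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  # opposite-signed errors cancel in MPE but not MAPE
  expect_equal(mpe(c(1, 3), c(2, 2)), 0)
  expect_equal(mape(c(1, 3), c(2, 2)), 1)
  expect_error(mpe(1:3, 1:4), class = "costsim_domain_error")
  expect_error(mape(numeric(), numeric()), class = "costsim_domain_error")

  expect_equal(mse_beta(rep(1, 5), 1), 0)
  expect_equal(mse_beta(c(0, 2), 1), 1)
  expect_error(mse_beta(numeric(), 1), class = "costsim_domain_error")
})

test_that("MAPE dominates |MPE| for every estimator on every dataset", {
  fitters <- list(
    function(d) fit_ols_log(d, "normal"),
    function(d) fit_ols_log(d, "smearing"),
    fit_gamma_glm, fit_weibull_reg, fit_cox_ph
  )
  for (fam in c("lognormal", "gamma", "weibull")) {
    for (s in 1:3) {
      d <- generate_costs(dgp_spec(fam, 0.5, n = 40), seed = 700 + s)
      for (f in fitters) {
        fit <- suppressWarnings(f(d))
        expect_gte(mape(d$y, fit$fitted$.fitted) + 1e-12,
                   abs(mpe(d$y, fit$fitted$.fitted)))
      }
    }
  }
})

test_that("the simulation interval follows the mean +/- 1.96 sd/sqrt(n) convention", {
  ci <- sim_interval(c(0.9, 1.0, 1.1), n_sample = 25)
  s <- sd(c(0.9, 1.0, 1.1))
  expect_equal(unname(ci["lower"]), 1 - 1.96 * s / 5, tolerance = 1e-12)
  expect_equal(unname(ci["upper"]), 1 + 1.96 * s / 5, tolerance = 1e-12)
  # half-width * sqrt(n) / 1.96 recovers the between-replication sd exactly
  expect_equal((ci["upper"] - ci["lower"]) / 2 * 5 / 1.96, c(upper = s),
               tolerance = 1e-12)
  # degenerate estimates give a zero-width interval
  expect_equal(unname(sim_interval(rep(2, 10), 25)), c(2, 2))
  # reference case: mean 1.0, sd 0.535, n = 25 -> (0.790, 1.210)
  b <- c(1 - 0.535 / sqrt(2), 1 + 0.535 / sqrt(2))  # mean 1, sd 0.535
  ci2 <- sim_interval(b, 25)
  expect_equal(unname(ci2), c(0.79028, 1.20972), tolerance = 1e-4)
})

test_that("the decile goodness-of-fit test is exact at zero error and calibrated", {
  y <- rgamma(50, 4, 2)
  hl0 <- hl_test(y, y, variance = rep(1, 50))
  expect_equal(hl0$statistic, 0)
  expect_equal(hl0$p.value, 1)
  expect_equal(hl0$df, 8)

  # heavily tied predictions merge groups with a warning
  expect_warning(
    hl_test(y, rep(c(1, 2), 25), variance = rep(1, 50)),
    class = "costsim_hl_merged"
  )
  expect_error(hl_test(y[1:10], y[1:10], variance = 1),
               class = "costsim_domain_error")

  # nominal rejection rate for a well-specified gamma fit
  R <- 300
  rej <- vapply(seq_len(R), function(r) {
    d <- generate_costs(dgp_spec("gamma", 2, n = 200), seed = 1000 + r)
    fit <- fit_gamma_glm(d)
    hl_test(d$y, fit$fitted$.fitted, model_variance(fit))$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / R))
})

test_that("residual decile profiles are flat at the residual's constant value", {
  x <- runif(50)
  prof0 <- residual_decile_profile(x, rep(1, 50), rep(1, 50))
  expect_equal(prof0$decile, 1:10)
  expect_equal(prof0$mean_residual, rep(0, 10))
  profc <- residual_decile_profile(x, rep(3, 50), rep(1, 50))
  expect_equal(profc$mean_residual, rep(2, 10))
  expect_error(residual_decile_profile(runif(5), rep(1, 5), rep(1, 5)),
               class = "costsim_domain_error")
})

test_that("an unbiased estimator's replication-averaged profile is flat at zero", {
  R <- 150
  profs <- vapply(seq_len(R), function(r) {
    d <- generate_costs(dgp_spec("gamma", 2, n = 100), seed = 3000 + r)
    fit <- fit_gamma_glm(d)
    residual_decile_profile(d$x, d$y, fit$fitted$.fitted)$mean_residual
  }, numeric(10))
  avg <- rowMeans(profs)
  se <- apply(profs, 1, sd) / sqrt(R)
  expect_true(all(abs(avg) < 4 * se))
})

test_that("sample moments use the moment skewness and raw kurtosis conventions", {
  y <- c(1, 2, 2, 3, 7)
  m <- mean(y); d <- y - m
  sm <- sample_moments(y)
  expect_equal(sm$mean, m)
  expect_equal(sm$sd, sd(y))
  expect_equal(sm$skewness, mean(d^3) / mean(d^2)^1.5)
  expect_equal(sm$kurtosis, mean(d^4) / mean(d^2)^2)

  # raw (non-excess) kurtosis tends to 3 for normal data
  set.seed(4)
  expect_equal(sample_moments(rnorm(1e5))$kurtosis, 3, tolerance = 0.1)

  expect_warning(smc <- sample_moments(rep(1, 10)),
                 class = "costsim_degenerate_sample")
  expect_equal(smc$sd, 0)
  expect_true(is.na(smc$skewness) && is.na(smc$kurtosis))
})

test_that("descriptive statistics average per-replication sample moments", {
  spec <- dgp_spec("gamma", 1, n = 50)
  ds <- lapply(1:10, function(s) generate_costs(spec, seed = s))
  row <- descriptive_stats(ds)
  manual <- colMeans(do.call(rbind, lapply(ds, function(d)
    as.matrix(sample_moments(d$y)))))
  expect_equal(row$mean, unname(manual["mean"]))
  expect_equal(row$sd, unname(manual["sd"]))
  expect_equal(row$skewness, unname(manual["skewness"]))
  expect_equal(row$n_replications, 10)
})
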