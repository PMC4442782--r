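test_that("child seeds are deterministic, distinct and in range", {
  s1 <- derive_seed(1, "lognormal", 0.5, 25, 1)
  expect_identical(s1, derive_seed(1, "lognormal", 0.5, 25, 1))
  expect_true(s1 >= 1 && s1 <= 2^31 - 1)
  seeds <- vapply(1:500, function(r) derive_seed(1, "gamma", 2, 100, r),
                  integer(1))
  expect_equal(length(unique(seeds)), 500)
  expect_false(derive_seed(1, "gamma", 2, 100, 1) ==
                 derive_seed(2, "gamma", 2, 100, 1))
  expect_false(derive_seed(1, "gamma", 2, 100, 1) ==
                 derive_seed(1, "gamma", 2, 50, 1))
})

test_that("cell aggregates at R = 2 equal hand-computed replication means", {
  cell <- run_cell("gamma", 2, n = 30, estimators = c("ols_log", "gamma_glm"),
                   replications = 2, root_seed = 77)
  spec <- dgp_spec("gamma", 2, n = 30)
  per_rep <- lapply(1:2, function(r) {
    d <- generate_costs(spec, seed = derive_seed(77, "gamma", 2, 30, r))
    fo <- fit_ols_log(d, "smearing")   # non-lognormal family -> smearing
    fg <- fit_gamma_glm(d)
    list(
      ols = c(mpe(d$y, fo$fitted$.fitted), mape(d$y, fo$fitted$.fitted),
              fo$beta1_hat),
      gam = c(mpe(d$y, fg$fitted$.fitted), mape(d$y, fg$fitted$.fitted),
              fg$beta1_hat),
      stats = unlist(sample_moments(d$y))
    )
  })
  ols <- dplyr::filter(cell$cells, estimator == "ols_log")
  expect_equal(ols$mpe, mean(c(per_rep[[1]]$ols[1], per_rep[[2]]$ols[1])))
  expect_equal(ols$mape, mean(c(per_rep[[1]]$ols[2], per_rep[[2]]$ols[2])))
  b_ols <- c(per_rep[[1]]$ols[3], per_rep[[2]]$ols[3])
  expect_equal(ols$mean_beta1, mean(b_ols))
  expect_equal(ols$mse_beta, mean((b_ols - 1)^2))
  expect_equal(unname(c(ols$ci_lower, ols$ci_upper)),
               unname(sim_interval(b_ols, 30)))
  gam <- dplyr::filter(cell$cells, estimator == "gamma_glm")
  b_gam <- c(per_rep[[1]]$gam[3], per_rep[[2]]$gam[3])
  expect_equal(gam$mse_beta, mean((b_gam - 1)^2))
  expect_equal(cell$descriptive$mean,
               mean(c(per_rep[[1]]$stats["mean"], per_rep[[2]]$stats["mean"])))
  expect_equal(cell$descriptive$sd,
               mean(c(per_rep[[1]]$stats["sd"], per_rep[[2]]$stats["sd"])))
})

test_that("a minimal grid has one descriptive row and one cell row per estimator", {
  cfg <- simulation_config(lognormal = 1, gamma = numeric(),
                           weibull = numeric(), sample_sizes = 25,
                           replications = 3, root_seed = 5)
  tab <- run_grid(cfg)
  expect_s3_class(tab, "cost_sim_table")
  expect_equal(nrow(tab$descriptives), 1)
  expect_equal(nrow(tab$cells), 4)
  expect_equal(nrow(tab$profiles), 40)
  expect_setequal(tab$cells$estimator,
                  c("ols_log", "gamma_glm", "weibull_reg", "cox_ph"))
  expect_equal(nrow(tidy(tab)), 4)
  expect_equal(glance(tab)$n_cells, 4)
})

test_that("grid results do not depend on cell execution order", {
  base <- list(sample_sizes = c(25, 50), replications = 4, root_seed = 9,
               estimators = c("ols_log", "gamma_glm"))
  cfg1 <- simulation_config(lognormal = c(0.5, 1), gamma = numeric(),
                            weibull = numeric(),
                            sample_sizes = base$sample_sizes,
                            replications = base$replications,
                            estimators = base$estimators,
                            root_seed = base$root_seed)
  cfg2 <- simulation_config(lognormal = c(1, 0.5), gamma = numeric(),
                            weibull = numeric(),
                            sample_sizes = rev(base$sample_sizes),
                            replications = base$replications,
                            estimators = base$estimators,
                            root_seed = base$root_seed)
  t1 <- run_grid(cfg1)
  t2 <- run_grid(cfg2)
  key <- c("family", "param", "n", "estimator")
  expect_equal(dplyr::arrange(t1$cells, dplyr::across(dplyr::all_of(key))),
               dplyr::arrange(t2$cells, dplyr::across(dplyr::all_of(key))))
})

test_that("reruns under a fixed root seed are identical, and caches resume runs", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(lognormal = numeric(), gamma = 1,
                           weibull = numeric(), sample_sizes = 25,
                           replications = 4, root_seed = 11,
                           output_dir = dir)
  t1 <- run_grid(cfg)
  expect_true(file.exists(file.path(dir, "cells", "gamma_1_n25.json")))
  t2 <- run_grid(cfg)  # served from cache
  expect_equal(t1$cells, t2$cells, tolerance = 1e-12)
  expect_equal(t1$descriptives, t2$descriptives, tolerance = 1e-12)

  # a different root seed must not reuse the cache
  cfg3 <- simulation_config(lognormal = numeric(), gamma = 1,
                            weibull = numeric(), sample_sizes = 25,
                            replications = 4, root_seed = 12,
                            output_dir = dir)
  t3 <- run_grid(cfg3)
  expect_false(isTRUE(all.equal(t1$cells$mean_beta1, t3$cells$mean_beta1)))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(lognormal = -1),
               class = "costsim_domain_error")
  expect_error(simulation_config(sample_sizes = c(25, 5)),
               class = "costsim_domain_error")
  expect_error(simulation_config(replications = 1),
               class = "costsim_domain_error")
  expect_error(simulation_config(lognormal = numeric(), gamma = numeric(),
                                 weibull = numeric()),
               class = "costsim_domain_error")
})
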