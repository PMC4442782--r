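# Monte Carlo engine. A "cell" is one (family, param, n) scenario; the grid
# is the full factorial over families, their parameter lists and the sample
# sizes. Replication seeds are derived from the cell's labels, never from
# iteration order, so any subset of the grid run in any order reproduces the
# same numbers.

ESTIMATORS <- c("ols_log", "gamma_glm", "weibull_reg", "cox_ph")

#' Deterministic child seed from a root seed and labels
#'
#' Hashes the root seed together with any number of labels (family,
#' parameter, sample size, replication index) into an integer in
#' `[1, 2^31 - 2]` by a multiplicative string hash modulo the Mersenne
#' prime `2^31 - 1`. The derivation depends only on the labels, so
#' replications and cells are reproducible independently of execution
#' order.
#'
#' @param root_seed Integer root seed of the whole run.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer seed.
#' @examples
#' derive_seed(1, "lognormal", 0.5, 25, 1)
#' @export
derive_seed <- function(root_seed, ...) {
  key <- paste(c(format(root_seed), vapply(list(...), function(v)
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v),
    character(1))), collapse = ":")
  bytes <- utf8ToInt(key)
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

fit_one <- function(estimator, data, retransform) {
  switch(estimator,
    ols_log = fit_ols_log(data, retransform = retransform),
    gamma_glm = fit_gamma_glm(data),
    weibull_reg = fit_weibull_reg(data),
    cox_ph = fit_cox_ph(data)
  )
}

#' Run one simulation cell
#'
#' Generates `replications` datasets from one scenario, fits each requested
#' estimator to every dataset, and aggregates the evaluation statistics.
#' Non-converged or failed fits are excluded from the aggregates and
#' counted; a cell in which more than 5% of an estimator's fits fail is
#' flagged.
#'
#' Retransformation policy for the log-scale OLS estimator: normal-theory
#' correction when the generating family is log-normal (the errors are then
#' exactly Gaussian on the log scale), Duan smearing otherwise. Override
#' with `retransform`.
#'
#' @param family,param Generating family and its parameter (see
#'   [dgp_spec()]).
#' @param n Per-replication sample size.
#' @param estimators Character subset of
#'   `c("ols_log", "gamma_glm", "weibull_reg", "cox_ph")`.
#' @param replications Number of Monte Carlo replications.
#' @param root_seed Root seed; replication `r` uses
#'   `derive_seed(root_seed, family, param, n, r)`.
#' @param beta1 Generating slope (default 1), also the truth used for
#'   `mse_beta`.
#' @param retransform `NULL` (family-based policy) or `"normal"` /
#'   `"smearing"` to force one.
#' @param hl_alpha Nominal level for the decile goodness-of-fit rejection
#'   rate.
#' @param diagnostics If `FALSE`, skip the decile goodness-of-fit test, the
#'   proportional-hazards diagnostic and the residual-by-decile profiles
#'   (their columns are `NA` / empty); the error and coefficient aggregates
#'   are unchanged. Useful for large precision-only runs.
#' @return A list with elements `descriptive` (one-row tibble of averaged
#'   sample statistics), `cells` (one row per estimator; see Details) and
#'   `profiles` (mean residual by covariate decile, averaged over
#'   replications, one row per estimator x decile).
#' @details Cell columns: `mpe`, `mape` (averaged over replications),
#'   `mse_beta` with its Monte Carlo standard error `se_mse_beta`,
#'   the 95% simulation interval (`ci_lower`, `ci_upper`), a supplementary
#'   percentile interval across replications (`pct_lower`, `pct_upper`),
#'   `mean_aic`, `hl_rejection_rate`, `mean_beta1`, `sd_beta1`,
#'   `mse_beta_ph` (Cox estimates against the proportional-hazards truth
#'   `-shape * beta1`, Weibull family only), `ph_rejection_rate` (Cox
#'   only), `n_replications`, `n_converged`, `flagged`.
#' @examples
#' run_cell("gamma", 1, n = 25, estimators = "gamma_glm",
#'          replications = 5, root_seed = 1)$cells
#' @export
run_cell <- function(family, param, n, estimators = ESTIMATORS,
                     replications, root_seed, beta1 = 1,
                     retransform = NULL, hl_alpha = 0.05,
                     diagnostics = TRUE) {
  estimators <- match.arg(estimators, ESTIMATORS, several.ok = TRUE)
  if (replications < 2) {
    abort("`replications` must be at least 2.", class = "costsim_domain_error")
  }
  spec <- dgp_spec(family, param, n = n, beta1 = beta1)
  retr <- retransform %||% if (family == "lognormal") "normal" else "smearing"
  R <- as.integer(replications)
  ne <- length(estimators)

  stat_names <- c("mean", "sd", "skewness", "kurtosis")
  stats_mat <- matrix(NA_real_, R, 4, dimnames = list(NULL, stat_names))
  beta1_m <- mpe_m <- mape_m <- aic_m <- hl_m <- php_m <-
    matrix(NA_real_, R, ne, dimnames = list(NULL, estimators))
  conv_m <- matrix(FALSE, R, ne, dimnames = list(NULL, estimators))
  prof_a <- array(NA_real_, c(R, 10, ne))

  for (r in seq_len(R)) {
    set.seed(derive_seed(root_seed, family, param, n, r))
    raw <- generate_costs_raw(spec)
    d <- data.frame(y = raw$y, x = raw$x)
    m <- mean(raw$y)
    dev <- raw$y - m
    m2 <- mean(dev^2)
    stats_mat[r, ] <- c(m, sd(raw$y),
                        if (m2 > 0) mean(dev^3) / m2^1.5 else NA_real_,
                        if (m2 > 0) mean(dev^4) / m2^2 else NA_real_)
    for (j in seq_len(ne)) {
      fit <- tryCatch(
        suppressWarnings(fit_one(estimators[j], d, retr)),
        error = function(e) NULL
      )
      if (is.null(fit) || !isTRUE(fit$converged) ||
          !is.finite(fit$beta1_hat)) {
        next
      }
      conv_m[r, j] <- TRUE
      yhat <- fit$fitted$.fitted
      beta1_m[r, j] <- fit$beta1_hat
      mpe_m[r, j] <- mean(raw$y - yhat)
      mape_m[r, j] <- mean(abs(raw$y - yhat))
      aic_m[r, j] <- fit$aic %||% NA_real_
      if (diagnostics) {
        if (n >= 20) {
          hl <- tryCatch(
            suppressWarnings(hl_test(raw$y, yhat, model_variance(fit))),
            error = function(e) NULL
          )
          if (!is.null(hl)) hl_m[r, j] <- hl$p.value
        }
        prof_a[r, , j] <- residual_decile_profile(raw$x, raw$y,
                                                  yhat)$mean_residual
        if (estimators[j] == "cox_ph") {
          php_m[r, j] <- tryCatch(
            suppressWarnings(ph_diagnostic(fit)),
            error = function(e) NA_real_
          )
        }
      }
    }
  }

  descriptive <- tibble::tibble(
    family = family, param = param, n = as.integer(n),
    mean = mean(stats_mat[, "mean"]),
    sd = mean(stats_mat[, "sd"]),
    skewness = mean(stats_mat[, "skewness"], na.rm = TRUE),
    kurtosis = mean(stats_mat[, "kurtosis"], na.rm = TRUE),
    n_replications = R
  )

  ph_truth <- if (family == "weibull") -param * beta1 else NA_real_

  cells <- purrr::map_dfr(seq_len(ne), function(j) {
    ok <- conv_m[, j]
    nc <- sum(ok)
    if (nc < 2L) {
      return(tibble::tibble(
        family = family, param = param, n = as.integer(n),
        estimator = estimators[j],
        mpe = NA_real_, mape = NA_real_, mse_beta = NA_real_,
        se_mse_beta = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
        pct_lower = NA_real_, pct_upper = NA_real_, mean_aic = NA_real_,
        hl_rejection_rate = NA_real_, mean_beta1 = NA_real_,
        sd_beta1 = NA_real_, mse_beta_ph = NA_real_,
        ph_rejection_rate = NA_real_,
        n_replications = R, n_converged = nc, flagged = TRUE
      ))
    }
    b <- beta1_m[ok, j]
    sq <- (b - beta1)^2
    ci <- sim_interval(b, n_sample = n)
    hl_p <- hl_m[ok, j]
    php <- php_m[ok, j]
    tibble::tibble(
      family = family, param = param, n = as.integer(n),
      estimator = estimators[j],
      mpe = mean(mpe_m[ok, j]),
      mape = mean(mape_m[ok, j]),
      mse_beta = mean(sq),
      se_mse_beta = sd(sq) / sqrt(nc),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      pct_lower = unname(quantile(b, 0.025)),
      pct_upper = unname(quantile(b, 0.975)),
      mean_aic = mean(aic_m[ok, j], na.rm = TRUE),
      hl_rejection_rate = if (all(is.na(hl_p))) NA_real_ else
        mean(hl_p < hl_alpha, na.rm = TRUE),
      mean_beta1 = mean(b),
      sd_beta1 = sd(b),
      mse_beta_ph = if (is.na(ph_truth) || estimators[j] != "cox_ph")
        NA_real_ else mean((b - ph_truth)^2),
      ph_rejection_rate = if (all(is.na(php))) NA_real_ else
        mean(php < 0.05, na.rm = TRUE),
      n_replications = R, n_converged = nc,
      flagged = nc < 0.95 * R
    )
  })

  profiles <- purrr::map_dfr(seq_len(ne), function(j) {
    ok <- conv_m[, j]
    tibble::tibble(
      family = family, param = param, n = as.integer(n),
      estimator = estimators[j],
      decile = 1:10,
      mean_residual = if (sum(ok) > 0)
        as.numeric(colMeans(prof_a[ok, , j, drop = FALSE], na.rm = TRUE))
      else rep(NA_real_, 10)
    )
  })

  list(descriptive = descriptive, cells = cells, profiles = profiles)
}

#' Configure a simulation grid
#'
#' Default grid: the 11 scenarios -- log-normal with log-scale variance
#' 0.5, 1, 1.5, 2; gamma with shape 0.5, 1, 2, 4; Weibull with shape
#' 0.5, 1, 5 -- crossed with sample sizes 25, 50, 100, 500, 1000, all four
#' estimators, 10,000 replications and slope 1.
#'
#' @param lognormal,gamma,weibull Numeric vectors of family parameters
#'   (empty vector drops a family).
#' @param sample_sizes Integer vector of per-replication sample sizes
#'   (each at least 10).
#' @param replications Replications per cell (at least 2).
#' @param beta1 Generating slope.
#' @param estimators Estimator subset.
#' @param root_seed Root seed of the run.
#' @param output_dir Optional directory: per-cell results are written there
#'   as they complete, and an interrupted [run_grid()] resumes from them.
#' @return A `simulation_config` list.
#' @examples
#' simulation_config(lognormal = 1, gamma = numeric(), weibull = numeric(),
#'                   sample_sizes = 25, replications = 10)
#' @export
simulation_config <- function(lognormal = c(0.5, 1, 1.5, 2),
                              gamma = c(0.5, 1, 2, 4),
                              weibull = c(0.5, 1, 5),
                              sample_sizes = c(25, 50, 100, 500, 1000),
                              replications = 10000,
                              beta1 = 1,
                              estimators = ESTIMATORS,
                              root_seed = 1L,
                              output_dir = NULL) {
  estimators <- match.arg(estimators, ESTIMATORS, several.ok = TRUE)
  params <- list(lognormal = lognormal, gamma = gamma, weibull = weibull)
  for (fam in names(params)) {
    if (length(params[[fam]]) && any(params[[fam]] <= 0)) {
      abort(sprintf("All `%s` parameters must be positive.", fam),
            class = "costsim_domain_error")
    }
  }
  if (!length(unlist(params))) {
    abort("At least one family parameter is required.",
          class = "costsim_domain_error")
  }
  if (any(sample_sizes < 10)) {
    abort("All sample sizes must be at least 10.",
          class = "costsim_domain_error")
  }
  if (replications < 2) {
    abort("`replications` must be at least 2.", class = "costsim_domain_error")
  }
  structure(
    list(params = params, sample_sizes = as.integer(sort(sample_sizes)),
         replications = as.integer(replications), beta1 = beta1,
         estimators = estimators, root_seed = as.integer(root_seed),
         output_dir = output_dir),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (fam in names(x$params)) {
    if (length(x$params[[fam]])) {
      cat(sprintf("  %s: %s\n", fam, paste(x$params[[fam]], collapse = ", ")))
    }
  }
  cat(sprintf("  n: %s | replications: %d | beta1: %g | seed: %d\n",
              paste(x$sample_sizes, collapse = ", "), x$replications,
              x$beta1, x$root_seed))
  cat(sprintf("  estimators: %s\n", paste(x$estimators, collapse = ", ")))
  invisible(x)
}

cell_key <- function(family, param, n) {
  sprintf("%s_%s_n%d", family, sprintf("%.10g", param), as.integer(n))
}

#' Run the full simulation grid
#'
#' Executes [run_cell()] for every (family, parameter, sample size)
#' combination in the config and assembles a `cost_sim_table`. Per-cell
#' seeds are derived from the cell's labels, so results are identical for
#' any execution order or grid subset. If `config$output_dir` is set, each
#' completed cell is serialized there as JSON and reused on re-runs with
#' the same root seed and replication count (interrupted runs resume).
#' Estimator failures within a replication are excluded and counted; a
#' failing cell never aborts the grid.
#'
#' @param config A [simulation_config()].
#' @param verbose If `TRUE`, log per-cell progress to stderr.
#' @param diagnostics Passed to [run_cell()]; set `FALSE` to skip the
#'   goodness-of-fit and proportional-hazards diagnostics and the residual
#'   profiles.
#' @return A `cost_sim_table`: list with tibbles `descriptives` (one row
#'   per scenario x n), `cells` (one row per scenario x n x estimator),
#'   `profiles` (residual-by-decile averages), plus `config` and
#'   `provenance`.
#' @examples
#' cfg <- simulation_config(lognormal = 1, gamma = numeric(),
#'                          weibull = numeric(), sample_sizes = 25,
#'                          replications = 5, root_seed = 42)
#' tab <- run_grid(cfg)
#' tidy(tab)
#' @export
run_grid <- function(config, verbose = FALSE, diagnostics = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  cache_dir <- NULL
  if (!is.null(config$output_dir)) {
    cache_dir <- file.path(config$output_dir, "cells")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  grid <- tidyr::expand_grid(
    scenario = purrr::list_flatten(purrr::imap(
      config$params,
      function(p, fam) purrr::map(p, ~ list(family = fam, param = .x))
    )),
    n = config$sample_sizes
  )

  results <- purrr::pmap(grid, function(scenario, n) {
    key <- cell_key(scenario$family, scenario$param, n)
    cached <- read_cell_cache(cache_dir, key, config)
    if (!is.null(cached)) {
      if (verbose) log_msg("cell %s: loaded from cache", key)
      return(cached)
    }
    if (verbose) log_msg("cell %s: %d replications ...", key,
                         config$replications)
    res <- run_cell(scenario$family, scenario$param, n,
                    estimators = config$estimators,
                    replications = config$replications,
                    root_seed = config$root_seed,
                    beta1 = config$beta1,
                    diagnostics = diagnostics)
    if (verbose) {
      log_msg("cell %s: done (%d/%d fits converged)", key,
              sum(res$cells$n_converged), nrow(res$cells) * config$replications)
    }
    write_cell_cache(cache_dir, key, config, res)
    res
  })

  tab <- structure(
    list(
      descriptives = purrr::map_dfr(results, "descriptive"),
      cells = purrr::map_dfr(results, "cells"),
      profiles = purrr::map_dfr(results, "profiles"),
      config = config,
      provenance = list(
        package = "costsim",
        version = as.character(utils::packageVersion("costsim")),
        root_seed = config$root_seed,
        replications = config$replications,
        seed_rule = "derive_seed(root_seed, family, param, n, replication)",
        n_failed_fits = NULL
      )
    ),
    class = "cost_sim_table"
  )
  tab$provenance$n_failed_fits <-
    sum(tab$cells$n_replications - tab$cells$n_converged)
  tab
}

log_msg <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

read_cell_cache <- function(cache_dir, key, config) {
  if (is.null(cache_dir)) return(NULL)
  path <- file.path(cache_dir, paste0(key, ".json"))
  if (!file.exists(path)) return(NULL)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(obj) || !identical(as.integer(obj$root_seed), config$root_seed) ||
      !identical(as.integer(obj$replications), config$replications)) {
    return(NULL)
  }
  list(descriptive = coerce_schema(obj$descriptive,
                                   int = c("n", "n_replications")),
       cells = coerce_schema(obj$cells,
                             int = c("n", "n_replications", "n_converged"),
                             lgl = "flagged"),
       profiles = coerce_schema(obj$profiles, int = c("n", "decile")))
}

# JSON round-trips lose column types (all-NA columns come back logical);
# restore the table schema: known integers/logicals, character keys, and
# everything else double.
coerce_schema <- function(df, int = character(), lgl = character(),
                          chr = c("family", "estimator")) {
  df <- tibble::as_tibble(df)
  for (nm in names(df)) {
    df[[nm]] <- if (nm %in% chr) as.character(df[[nm]])
      else if (nm %in% int) as.integer(df[[nm]])
      else if (nm %in% lgl) as.logical(df[[nm]])
      else as.numeric(df[[nm]])
  }
  df
}

write_cell_cache <- function(cache_dir, key, config, res) {
  if (is.null(cache_dir)) return(invisible(NULL))
  path <- file.path(cache_dir, paste0(key, ".json"))
  jsonlite::write_json(
    list(root_seed = config$root_seed, replications = config$replications,
         descriptive = res$descriptive, cells = res$cells,
         profiles = res$profiles),
    path, digits = NA, na = "null"
  )
  invisible(path)
}

#' @export
print.cost_sim_table <- function(x, ...) {
  cat(sprintf(
    "<cost_sim_table> %d scenarios x %d sample sizes, %d estimator cells (%d replications each)\n",
    nrow(dplyr::distinct(x$descriptives, .data$family, .data$param)),
    length(unique(x$descriptives$n)), nrow(x$cells),
    x$config$replications))
  cat(sprintf("  failed fits: %d | root seed: %d\n",
              x$provenance$n_failed_fits, x$provenance$root_seed))
  invisible(x)
}

#' Estimator-level results of a simulation grid
#'
#' @param x A `cost_sim_table`.
#' @param ... Unused.
#' @return The `cells` tibble: one row per (family, param, n, estimator).
#' @export
tidy.cost_sim_table <- function(x, ...) x$cells

#' One-row summary of a simulation grid
#'
#' @param x A `cost_sim_table`.
#' @param ... Unused.
#' @return A one-row tibble with grid dimensions and failure counts.
#' @export
glance.cost_sim_table <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(dplyr::distinct(x$descriptives, .data$family,
                                       .data$param)),
    n_sample_sizes = length(unique(x$descriptives$n)),
    n_cells = nrow(x$cells),
    replications = x$config$replications,
    n_failed_fits = x$provenance$n_failed_fits,
    root_seed = x$provenance$root_seed
  )
}
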