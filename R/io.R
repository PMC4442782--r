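# Delimited-text interfaces: cost datasets in and out (header "y,x"),
# per-fit predictions, and the simulation grid's table files plus a JSON
# run manifest. All CSVs are comma-separated, "." decimal, UTF-8, header
# row, no index column.

#' Read a cost dataset from delimited text
#'
#' Expects a header row with at least columns `y` and `x`; extra columns
#' are kept but ignored by the estimators.
#'
#' @param path File path.
#' @return A tibble with columns `y` and `x` first.
#' @export
read_cost_data <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("y", "x") %in% names(d))) {
    abort(sprintf("`%s` must have columns `y` and `x`.", path),
          class = "costsim_domain_error")
  }
  dplyr::relocate(d, "y", "x")
}

#' Write a cost dataset as delimited text
#'
#' @param data Data frame with columns `y` and `x`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cost_data <- function(data, path) {
  validate_cost_data(data, require_positive_y = FALSE, min_n = 1L)
  readr::write_csv(dplyr::select(as.data.frame(data), "y", "x"), path)
  invisible(path)
}

#' Write per-observation predictions of a fit
#'
#' @param fit A `cost_fit`.
#' @param path Output file path.
#' @return `path`, invisibly. Columns: `y`, `yhat`, `residual`.
#' @export
write_predictions <- function(fit, path) {
  stopifnot(inherits(fit, "cost_fit"))
  out <- tibble::tibble(y = fit$fitted$y, yhat = fit$fitted$.fitted,
                        residual = fit$fitted$.resid)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a simulation grid as per-sample-size tables
#'
#' Produces `table1.csv` (descriptive statistics of the generated costs,
#' one row per scenario x sample size), one `table_n<k>.csv` per sample
#' size (one row per scenario x estimator, columns in the order MPE, MAPE,
#' MSE of the slope, simulation-interval bounds, mean AIC, decile
#' goodness-of-fit rejection rate, followed by the supplementary columns),
#' `profiles.csv` (residual-by-decile averages for figures) and
#' `manifest.json` (config echo, seed rule, version, per-cell failure
#' counts) -- enough to reproduce the run exactly.
#'
#' @param table A `cost_sim_table` from [run_grid()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_tables <- function(table, dir) {
  stopifnot(inherits(table, "cost_sim_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(table$descriptives, file.path(dir, "table1.csv"))
  paper_order <- c("family", "param", "estimator", "mpe", "mape",
                   "mse_beta", "ci_lower", "ci_upper", "mean_aic",
                   "hl_rejection_rate")
  for (k in sort(unique(table$cells$n))) {
    rows <- dplyr::filter(table$cells, .data$n == k)
    rows <- dplyr::relocate(rows, dplyr::all_of(paper_order))
    readr::write_csv(dplyr::select(rows, -"n"),
                     file.path(dir, sprintf("table_n%d.csv", k)))
  }
  readr::write_csv(table$profiles, file.path(dir, "profiles.csv"))
  manifest <- list(
    config = list(
      params = table$config$params,
      sample_sizes = table$config$sample_sizes,
      replications = table$config$replications,
      beta1 = table$config$beta1,
      estimators = table$config$estimators,
      root_seed = table$config$root_seed
    ),
    provenance = table$provenance,
    cell_failures = dplyr::select(
      table$cells, "family", "param", "n", "estimator",
      "n_replications", "n_converged", "flagged"
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
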