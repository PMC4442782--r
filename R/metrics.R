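# Evaluation statistics: per-fit prediction errors, across-replication
# coefficient summaries, a decile goodness-of-fit test and residual
# profiles. All are estimator-agnostic: they see only (y, yhat, beta1_hat).

check_same_length <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    abort("`y` and `yhat` must have the same length.",
          class = "costsim_domain_error")
  }
  if (length(y) < 1L) {
    abort("At least one observation is required.",
          class = "costsim_domain_error")
  }
}

#' Mean prediction error (bias)
#'
#' `mean(y - yhat)`: the signed average gap between observed and predicted
#' cost, on the original scale. Values near zero indicate unbiased mean
#' prediction; the sign says whether the model under- (positive) or
#' over-predicts (negative).
#'
#' @param y Observed costs.
#' @param yhat Predicted mean costs (same length).
#' @return A scalar.
#' @examples
#' mpe(c(1, 3), c(2, 4))  # -1
#' @export
mpe <- function(y, yhat) {
  check_same_length(y, yhat)
  mean(y - yhat)
}

#' Mean absolute prediction error (individual accuracy)
#'
#' `mean(|y - yhat|)`: the average absolute gap between observed and
#' predicted cost. Unlike [mpe()], errors of opposite sign do not cancel,
#' so `mape(y, yhat) >= |mpe(y, yhat)|` always.
#'
#' @inheritParams mpe
#' @return A scalar.
#' @examples
#' mape(c(1, 2, 3), c(2, 2, 2))  # 2/3
#' @export
mape <- function(y, yhat) {
  check_same_length(y, yhat)
  mean(abs(y - yhat))
}

#' Mean squared error of the slope across replications
#'
#' `mean((beta1_hat - beta1_true)^2)` over replications. The truth is the
#' generating slope (1 in the standard grid) for every estimator, including
#' the Cox model -- whose estimand is a log hazard ratio, not the log-mean
#' slope, so its MSE is dominated by that scale mismatch (under the Weibull
#' family the Cox population coefficient is `-shape * beta1`; see
#' [true_cox_coefficient()] for the matching truth).
#'
#' @param beta1_hats Slope estimates, one per replication.
#' @param beta1_true Generating slope.
#' @return A scalar.
#' @examples
#' mse_beta(c(0, 2), 1)  # 1
#' @export
mse_beta <- function(beta1_hats, beta1_true) {
  if (length(beta1_hats) < 1L) {
    abort("At least one estimate is required.", class = "costsim_domain_error")
  }
  mean((beta1_hats - beta1_true)^2)
}

#' 95% simulation interval for the slope
#'
#' `mean(beta1_hats) +/- 1.96 * sd(beta1_hats) / sqrt(n_sample)`, where
#' `n_sample` is the per-replication sample size -- not the number of
#' replications. The between-replication standard deviation estimates the
#' sampling standard deviation of the estimator at that sample size, so the
#' interval mimics the 95% confidence interval a single study of size
#' `n_sample` would report around the average estimate.
#'
#' @param beta1_hats Slope estimates across replications (at least 2).
#' @param n_sample Per-replication sample size.
#' @return Named numeric vector `c(lower, upper)`. A degenerate set of
#'   identical estimates gives a zero-width interval.
#' @examples
#' sim_interval(c(0.9, 1.0, 1.1), n_sample = 25)
#' @export
sim_interval <- function(beta1_hats, n_sample) {
  if (length(beta1_hats) < 2L) {
    abort("At least two estimates are required.", class = "costsim_domain_error")
  }
  if (n_sample < 2) {
    abort("`n_sample` must be at least 2.", class = "costsim_domain_error")
  }
  m <- mean(beta1_hats)
  half <- 1.96 * sd(beta1_hats) / sqrt(n_sample)
  c(lower = m - half, upper = m + half)
}

#' Decile goodness-of-fit test for continuous cost predictions
#'
#' An adaptation of the Hosmer-Lemeshow grouping idea to continuous
#' outcomes: observations are grouped into deciles of the predicted mean;
#' within each group the statistic compares observed and predicted totals,
#' scaled by the model-implied variance:
#' `sum_g (O_g - E_g)^2 / V_g`, with `O_g = sum(y)`, `E_g = sum(yhat)` and
#' `V_g = sum(variance_i)`. The p-value is chi-squared with `groups - 2`
#' degrees of freedom (8 for the usual 10 groups). The chi-squared
#' reference is approximate for this adaptation; rejection rates near the
#' nominal level for well-specified models are the intended calibration
#' check.
#'
#' @inheritParams mpe
#' @param variance Model-based conditional variances, one per observation
#'   (see [model_variance()]), or a function of `yhat` returning them.
#' @param groups Number of prediction-quantile groups (default 10).
#' @return A list of class `costsim_hl`: `statistic`, `df`, `p.value`,
#'   `groups`. When ties in `yhat` leave fewer distinct quantile breaks
#'   than requested, adjacent groups are merged with a warning.
#' @examples
#' y <- rgamma(100, 2, 2); hl_test(y, rep(mean(y), 100), variance = var(y))
#' @export
hl_test <- function(y, yhat, variance, groups = 10L) {
  check_same_length(y, yhat)
  n <- length(y)
  if (n < 2L * groups) {
    abort(sprintf("At least %d observations are required for %d groups.",
                  2L * groups, groups), class = "costsim_domain_error")
  }
  v <- if (is.function(variance)) variance(yhat) else variance
  if (length(v) == 1L) v <- rep(v, n)
  check_same_length(yhat, v)
  breaks <- unique(quantile(yhat, probs = seq(0, 1, length.out = groups + 1)))
  if (length(breaks) < groups + 1L) {
    warn("Tied predictions: merging adjacent prediction groups.",
         class = "costsim_hl_merged")
  }
  if (length(breaks) < 3L) {
    # all predictions identical: a single group, compare totals directly
    g <- rep(1L, n)
  } else {
    g <- cut(yhat, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  o <- tapply(y, g, sum)
  e <- tapply(yhat, g, sum)
  vg <- tapply(v, g, sum)
  stat <- sum((o - e)^2 / vg)
  k <- length(o)
  df <- max(k - 2L, 1L)
  structure(
    list(statistic = stat, df = df,
         p.value = pchisq(stat, df = df, lower.tail = FALSE),
         groups = k),
    class = "costsim_hl"
  )
}

#' @export
print.costsim_hl <- function(x, ...) {
  cat(sprintf(
    "Decile goodness-of-fit: X2 = %.4f on %d df (%d groups), p = %.4f\n",
    x$statistic, x$df, x$groups, x$p.value))
  invisible(x)
}

#' Mean residual across deciles of the covariate
#'
#' Splits observations into ten groups by empirical deciles of `x` (ties go
#' to the lower decile) and returns the mean original-scale residual
#' `y - yhat` in each. Averaged over replications, a flat profile at zero
#' indicates no systematic bias pattern along the covariate.
#'
#' @param x Covariate values.
#' @param y Observed costs.
#' @param yhat Predicted mean costs.
#' @return A tibble with columns `decile` (1-10) and `mean_residual`.
#' @examples
#' residual_decile_profile(runif(50), rep(1, 50), rep(1, 50))
#' @export
residual_decile_profile <- function(x, y, yhat) {
  check_same_length(y, yhat)
  check_same_length(x, y)
  if (length(x) < 10L) {
    abort("At least 10 observations are required.",
          class = "costsim_domain_error")
  }
  g <- decile_index(x)
  res <- y - yhat
  means <- vapply(1:10, function(k) {
    idx <- g == k
    if (any(idx)) mean(res[idx]) else NA_real_
  }, numeric(1))
  tibble::tibble(decile = 1:10, mean_residual = means)
}

# Decile index 1..10 by empirical quantiles; ties on a break fall to the
# lower decile (cut with right-closed intervals).
decile_index <- function(x) {
  breaks <- quantile(x, probs = seq(0, 1, 0.1), names = FALSE)
  breaks <- unique(breaks)
  cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

#' Sample moments of one cost sample
#'
#' Mean, standard deviation (`n - 1` denominator), moment coefficient of
#' skewness `m3 / m2^(3/2)` and raw (non-excess) kurtosis `m4 / m2^2`,
#' where `m_k` are central sample moments with denominator `n`. Raw
#' kurtosis tends to 3 for large normal samples. A constant sample has
#' undefined skewness/kurtosis: both are returned as `NA` with a warning.
#'
#' @param y Numeric vector of costs.
#' @return One-row tibble: `mean`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' sample_moments(rgamma(1000, shape = 4))
#' @export
sample_moments <- function(y) {
  if (length(y) < 2L) {
    abort("At least two observations are required.",
          class = "costsim_domain_error")
  }
  m <- mean(y)
  d <- y - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    warn("Constant sample: skewness and kurtosis are undefined.",
         class = "costsim_degenerate_sample")
    return(tibble::tibble(mean = m, sd = 0, skewness = NA_real_,
                          kurtosis = NA_real_))
  }
  tibble::tibble(
    mean = m,
    sd = sd(y),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2
  )
}

#' Average descriptive statistics over replications
#'
#' Computes [sample_moments()] for each replication and averages them,
#' giving one descriptive row per scenario (the per-replication sample
#' statistics are averaged, not pooled; with heavy-tailed families the
#' average sample skewness at small `n` is well below the population
#' skewness, and grows with `n`).
#'
#' @param datasets A list of data frames with a `y` column (e.g. from
#'   [generate_costs()]), all of the same size.
#' @return One-row tibble: `mean`, `sd`, `skewness`, `kurtosis`,
#'   `n_replications`.
#' @examples
#' spec <- dgp_spec("gamma", 1, n = 50)
#' descriptive_stats(lapply(1:20, function(s) generate_costs(spec, s)))
#' @export
descriptive_stats <- function(datasets) {
  if (!length(datasets)) {
    abort("At least one dataset is required.", class = "costsim_domain_error")
  }
  rows <- purrr::map(datasets, ~ sample_moments(.x$y))
  dplyr::bind_rows(rows) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean)) |>
    dplyr::mutate(n_replications = length(datasets))
}
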