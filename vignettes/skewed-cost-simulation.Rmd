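---
title: "Comparing mean-cost estimators on skewed data: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mean-cost estimators on skewed data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costsim)
```

# The problem

Healthcare expenditures are strictly positive and strongly right skewed: a
few patients consume a large share of resources. Analysts nevertheless need
the *arithmetic mean* cost, on the original money scale, and how it moves
with covariates — budgets and policy effects are sums, not medians. Fitting
ordinary least squares to `log(y)` tames the skewness but answers the wrong
question: the retransformed prediction targets the geometric mean unless a
correction is applied, and the correction depends on the error distribution.
Generalized linear models with a log link target `E(y | x)` directly, and
the Cox proportional hazards model has sometimes been pressed into service
by treating cost as a "survival time".

`costsim` implements a seeded Monte Carlo test bench for this question: it
generates standardized skewed cost data under three families, fits four
estimators that all emit original-scale mean predictions under one
contract, and aggregates the comparison statistics into tables and figures.
Only fully observed, strictly positive costs are in scope: no zero-mass
(two-part) structure and no censoring.

# Data-generating processes

Each scenario draws a single covariate `x ~ Uniform(0, 1)` and a cost `y`
with log-linear scale structure, slope `beta1 = 1` by default:

* **log-normal**: `y = exp(beta0 + beta1 x + e)`, `e ~ N(0, sigma2)`,
  `sigma2 in {0.5, 1, 1.5, 2}`. Conditional skewness
  `(exp(sigma2) + 2) sqrt(exp(sigma2) - 1)` grows with the variance.
* **gamma**: `y ~ Gamma(shape = a, scale = exp(beta0 + beta1 x))`,
  `a in {0.5, 1, 2, 4}`. Conditional skewness `2 / sqrt(a)` falls as the
  shape grows; `a = 1` is the exponential special case.
* **Weibull**: `y ~ Weibull(shape = a, scale = exp(beta0 + beta1 x))`,
  `a in {0.5, 1, 5}`. This family has *exactly* proportional hazards in
  `x`: the population Cox log hazard ratio is `-a * beta1`
  (`true_cox_coefficient()`), which is what makes it the fair test bed for
  the Cox model. `a = 1` is again exponential.

**Standardization.** The intercept is never free. `solve_intercept()` sets
`beta0` so the *marginal* mean cost is exactly 1, e.g.
`beta0 = -log(a * (exp(beta1) - 1) / beta1)` for the gamma family (the
factor `(exp(b) - 1) / b` is the mean of `exp(b x)` over uniform `x`, with
limit 1 at `b = 0`). Bias metrics are therefore on a common scale across
all scenarios: an MPE of −0.1 always means "10% of the mean cost". A
quadrature fallback (`method = "quadrature"`) solves the same equation by
numerical integration and is tested to agree with the closed form to
1e−10.

`theoretical_moments()` exposes the closed-form marginal standard
deviation (which accounts for the uniform-`x` mixture, not just the
conditional distribution) and the conditional-on-`x` skewness. Note one
convention choice: Weibull skewness is reported as the standard
*standardized* third central moment; an unnormalized third-moment
expression is sometimes seen in print, but it is scale-dependent and not
comparable across families.

```{r}
theoretical_moments(dgp_spec("lognormal", 1, n = 1000))
```

A note on the printed equation conventions this package deliberately does
not follow: the log-normal "true model" is implemented with the covariate
term `beta1 * x` (a model without `x` would make the slope-recovery study
vacuous, and the conditional-mean formula `exp(beta0 + beta1 x +
0.5 sigma2)` requires it), and the Weibull density uses the standard
exponent `a - 1`, which is the density consistent with the mean
`b * gamma(1 + 1/a)`.

# The four estimators

All fitters take a data frame with columns `y`, `x` and return a
`cost_fit` exposing `(beta1_hat, yhat)` plus model-specific auxiliaries, so
the metrics layer is estimator-agnostic.

**Log-scale OLS with retransformation** (`fit_ols_log()`): least squares of
`log(y)` on `(1, x)`; `sigma2_hat = SSR / (n - 2)`. Predictions are
retransformed either by the normal-theory factor `exp(0.5 sigma2_hat)`
(exact when log-scale errors are Gaussian) or by Duan's smearing factor
`mean(exp(residual))` (consistent under any homoscedastic error). The
simulation pipeline picks normal-theory under the log-normal family and
smearing otherwise; both can be forced. Under heteroscedasticity neither is
consistent — out of scope here, where all generators are homoscedastic on
the log scale.

**Gamma GLM, log link** (`fit_gamma_glm()`): the exponential conditional
mean model `E(y|x) = exp(beta0 + beta1 x)` fitted by IRLS, i.e. the
quasi-maximum-likelihood score equations `sum((y - mu)/mu) = 0`,
`sum(x (y - mu)/mu) = 0`. Quasi-ML needs only the mean-variance
relationship `Var ∝ mu^2`, so the slope is consistent under all three
generating families. Dispersion is Pearson `/(n - 2)`; the reported AIC
evaluates the gamma likelihood at the quasi-ML coefficients with the shape
profiled out by maximum likelihood.

**Weibull regression** (`fit_weibull_reg()`): full ML (uncensored
accelerated-failure form) with log-linear scale and common shape. The
prediction is deliberately the fitted *scale* `exp(beta0_hat + beta1_hat x)`
— the exponential-conditional-mean reading of the model — which differs
from the true conditional mean by the factor `gamma(1 + 1/a)`. That
induces a *systematic* MPE of `1 - 1/gamma(1 + 1/a)` (+0.5 at shape 0.5,
−0.089 at shape 5, zero in the exponential case), a deliberate feature of
the comparison: it shows what treating a Weibull fit as an ECM costs.
`mean_correction = TRUE` multiplies the factor back in for users who want
the exact mean.

**Cox proportional hazards** (`fit_cox_ph()`): costs enter as fully
observed event times; the slope maximizes the Breslow-ties partial
likelihood. Mean predictions integrate the fitted survival curve,
`S(t|x) = exp(-H0(t) exp(beta1_hat x))` with `H0` the Breslow baseline
cumulative hazard, exactly over the step function and *truncated at the
largest observed cost* — no tail extrapolation. The truncation makes the
prediction slightly conservative in heavy-tailed samples but never
explosive; no prediction convention for the Cox model dominates here, and
the restricted mean is the choice that uses only what the semi-parametric
fit actually estimates. The intercept is absorbed by the baseline and
stored as 0 with a `beta0_undefined` flag. With a constant covariate the
partial likelihood is uninformative: the fit returns slope 0 and predicts
the sample mean (the restricted mean of the no-covariate survival estimate
on uncensored data).

Two different estimands meet in the Cox column: its coefficient is a log
*hazard* ratio, `-a * beta1` under the Weibull family, not the log-mean
slope `beta1`. The headline MSE therefore measures that scale mismatch
(≈ 36 at shape 5) rather than sampling noise; a supplementary column
(`mse_beta_ph`) scores the Cox slope against its own proportional-hazards
truth, where it is accurate.

# Evaluation statistics and conventions

Per fit: `mpe()` (mean `y - yhat`, bias), `mape()` (mean absolute error;
always at least `|MPE|`). Across replications: `mse_beta()` about the
generating slope, and the **simulation interval**
`mean(beta1_hat) ± 1.96 sd(beta1_hat) / sqrt(n)` with `n` the
*per-replication sample size* — the between-replication spread estimates
the estimator's sampling sd at that `n`, so the interval mimics a single
study's confidence interval; a percentile interval across replications is
emitted alongside. Descriptive rows average per-sample moments (sd with
`n - 1`, moment skewness, raw non-excess kurtosis — it tends to 3 for
normal data). Averages of sample skewness at small `n` sit well below the
population skewness for heavy-tailed families and climb with `n`; that is
a property of the statistic, not a bug.

The goodness-of-fit check (`hl_test()`) adapts the Hosmer–Lemeshow idea to
continuous outcomes: group by deciles of the prediction and compare
observed and expected group totals scaled by model-implied variances
(`model_variance()`), against chi-squared with `groups - 2` degrees of
freedom. The reference distribution is approximate; in simulation the
rejection rate for well-specified fits sits at the nominal 5% (the test
suite checks this), and the rate is reported per cell as the proportion of
replications rejecting at 0.05. `residual_decile_profile()` averages
residuals within deciles of `x` (ties to the lower decile); replication
averages of these profiles are what the figure functions draw —
re-fitting never happens in the plotting path.

# The engine: seeds, failures, reproducibility

`run_cell()` runs one `(family, param, n)` scenario; `run_grid()` runs the
full factorial (default: 11 scenarios × 5 sample sizes × 4 estimators,
10,000 replications). Replication `r` of a cell seeds the RNG with
`derive_seed(root_seed, family, param, n, r)` — a hash of the *labels*,
not the iteration order — so any subset of the grid, run in any order or
resumed from the per-cell JSON cache (`output_dir`), reproduces identical
numbers. Fits that fail or do not converge (iteration caps: 100; IRLS
deviance tolerance 1e−12) are excluded from aggregates and counted;
a cell with more than 5% exclusions for an estimator is flagged, and grid
execution never aborts on a cell failure. Seeds are 31-bit hashes, so
distinct labels can collide with probability ≈ `k^2 / 2^32` among `k`
streams — immaterial at this study's scale.

`simulation_config()` defaults *are* the study conditions: parameter lists
`{0.5, 1, 1.5, 2}` (log-normal variance), `{0.5, 1, 2, 4}` (gamma shape),
`{0.5, 1, 5}` (Weibull shape), sample sizes `{25, 50, 100, 500, 1000}`,
slope 1, 10,000 replications. The test suite and the acceptance script run
reduced replication counts (200–2,000 per cell, chosen so each check's
Monte Carlo standard error is a small fraction of its tolerance: the MC
standard error of an MSE estimate is about `MSE * sqrt(2/R)`, and of a
mean-MPE estimate `sd(MPE_r)/sqrt(R)`). The grid-wide property checks use
500 replications and compare adjacent sample sizes with a
three-standard-error allowance computed from the per-replication squared
errors — at finite `R`, strict sample monotonicity of a bias-dominated MSE
(the Cox cells) is not an almost-sure event even though the population
quantity is monotone.

# What the generator does and does not emulate

The synthetic data reproduce the structural features the comparison needs:
strict positivity, controlled right skewness spanning mild (gamma shape 4)
to extreme (log-normal variance 2), a log-linear covariate effect, and one
family with exact proportional hazards. They do *not* emulate several
features of real claims data: zero-cost mass, heteroscedasticity on the
log scale, multiple or discrete covariates, measurement error, or
censoring. Passing results therefore speak to estimator behaviour under
clean skewness and a correct single-covariate mean model — the
retransformation and estimand effects isolated here are real, but relative
rankings can change under heteroscedasticity or zero inflation, which this
package deliberately does not model.

# Known limitations

* One covariate is exercised throughout; the data model would extend, but
  no multi-covariate design is implemented or tested.
* AIC values use each family's own likelihood scale (log-scale Gaussian
  for log-OLS with 3 parameters, gamma with profiled shape and 3, Weibull
  with 3, partial likelihood with 1 for Cox); they are comparable within
  an estimator across scenarios, only cautiously across estimators.
* The decile goodness-of-fit p-value is an approximation; it is calibrated
  in simulation at the nominal level but is not an exact test.
* The Cox restricted-mean prediction depends on the largest observed cost;
  in very small samples from heavy-tailed scenarios it can understate the
  mean even when the hazard model is right.

# A worked example

```{r, eval = FALSE}
cfg <- simulation_config(
  lognormal = c(0.5, 1), gamma = numeric(), weibull = numeric(),
  sample_sizes = c(25, 100), replications = 2000, root_seed = 42
)
tab <- run_grid(cfg)
tidy(tab)                       # one row per scenario x n x estimator
write_sim_tables(tab, "out/")   # table1.csv, table_n25.csv, ..., manifest
autoplot(tab, family = "lognormal", n = 25)
```

The same pipeline is exposed on the command line
(`inst/cli/costsim.R`): `simulate` writes the tables and a JSON manifest
sufficient to reproduce the run, `figures` renders the residual-by-decile
panels from `profiles.csv`, and `describe` prints the solved intercept and
closed-form moments for any scenario.
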