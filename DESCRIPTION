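Package: costsim
Title: Monte Carlo Comparison of Regression Estimators for Skewed
    Healthcare Cost Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing regression estimators of
    mean healthcare cost when costs are strictly positive and right
    skewed. Generates mean-standardized cost data from log-normal, Gamma
    and Weibull data-generating processes with a single uniform covariate;
    fits log-scale ordinary least squares with normal-theory or smearing
    retransformation, a log-link Gamma generalized linear model, Weibull
    regression, and the Cox proportional hazards model with Breslow
    baseline restricted-mean predictions; and summarises bias (mean
    prediction error), accuracy (mean absolute prediction error),
    coefficient mean squared error, simulation intervals, information
    criteria and a decile-based goodness-of-fit diagnostic over a
    reproducible, seeded simulation grid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
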