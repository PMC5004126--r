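Package: nitratemodes
Title: Mode Decomposition of High-Frequency Stream Nitrate Time Series
Version: 0.1.0
Authors@R: person("Vollnkirchen", "Analytics", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Non-temporal knowledge discovery for high-frequency in-stream
    nitrate sensor records. Splits each sensor series into a seasonal baseline
    and a high-frequency residual by Fourier low-pass filtering, estimates the
    residual's empirical density by Pareto Density Estimation, decomposes it
    into concentration modes with a one-dimensional Gaussian mixture model
    (EM fitting, AIC/BIC model selection, Bayes posterior classification,
    chi-square/Kolmogorov-Smirnov goodness of fit), and characterises each
    mode by the synchronous environmental covariates using Bonferroni-corrected
    Welch t-tests. Includes a synthetic multivariate sensor-table generator
    with Markov regime switching so the whole pipeline is testable without
    field data, plus CSV input/output, cadence alignment, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
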