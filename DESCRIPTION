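Package: superstat
Title: Superstatistical Analysis of Environmental Sensor Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for superstatistical analysis of uniformly sampled
    environmental sensor time series such as dissolved oxygen and electrical
    conductivity records from river monitoring stations. Separates trend from
    fluctuations by centred moving-average (seasonal) detrending or by
    empirical mode decomposition, extracts the long timescale T on which
    fluctuations are locally Gaussian from the average-kurtosis curve, the
    short relaxation timescale tau from autocorrelation decay, and per-window
    inverse-variance (beta) values. Provides densities, samplers, and
    maximum-likelihood fitters for candidate beta-distributions (chi-squared,
    inverse chi-squared, log-normal, and a two-component chi-squared mixture
    sharing a common scale) and for the heavy-tailed q-Gaussian marginal,
    with AIC-based model comparison. A synthetic-data generator produces
    series with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse
Config/testthat/edition: 3
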