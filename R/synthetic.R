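#' Configuration for the synthetic superstatistical generator
#'
#' Bundles the generator settings: an additive deterministic trend (daily and
#' seasonal sinusoids plus linear drift) and a fluctuation process that is
#' locally Gaussian with inverse variance `beta` redrawn at the start of each
#' epoch of length `T_true_hours` from a configurable law, with a short
#' autoregressive relaxation time `tau_true_hours << T_true_hours`.
#'
#' Defaults emulate a year of 15-min dissolved-oxygen-like data: daily
#' amplitude 1.5 and seasonal amplitude 2 (units of the simulated parameter,
#' e.g. mg/L), no drift, `T_true = 16 h`, `tau_true = 1 h`, and a log-normal
#' beta-law with `sigma_ln = 1` centred so the median local variance is 1.
#'
#' @param step_minutes Sampling step (default 15).
#' @param duration_days Record length (default 365).
#' @param daily_amplitude,seasonal_amplitude Sinusoid amplitudes.
#' @param drift_slope Linear drift in units/day (default 0).
#' @param T_true_hours Epoch length on which beta is redrawn (default 16).
#' @param tau_true_hours Fluctuation relaxation time (default 1); `0` gives
#'   i.i.d. noise.
#' @param beta_law One of `"fixed"`, `"lognormal"`, `"chi2"`,
#'   `"chi2_mixture"`.
#' @param beta_params Named list of parameters for `beta_law`.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `superstat_config`.
#' @export
synthetic_config <- function(step_minutes = 15, duration_days = 365,
                             daily_amplitude = 1.5, seasonal_amplitude = 2,
                             drift_slope = 0,
                             T_true_hours = 16, tau_true_hours = 1,
                             beta_law = "lognormal",
                             beta_params = list(mu_ln = 0, sigma_ln = 1),
                             seed = 1L) {
  stopifnot(step_minutes > 0, duration_days > 0, T_true_hours > 0,
            tau_true_hours >= 0)
  if (tau_true_hours >= T_true_hours) {
    abort("tau_true must be smaller than T_true (timescale separation)",
          class = "superstat_config_error")
  }
  structure(
    list(step_minutes = step_minutes, duration_days = duration_days,
         daily_amplitude = daily_amplitude,
         seasonal_amplitude = seasonal_amplitude,
         drift_slope = drift_slope, T_true_hours = T_true_hours,
         tau_true_hours = tau_true_hours, beta_law = beta_law,
         beta_params = beta_params, seed = as.integer(seed)),
    class = "superstat_config"
  )
}

#' Generate a synthetic superstatistical time series
#'
#' Produces `series = trend + fluctuations` on a uniform grid. The trend is
#' `daily_amplitude * sin(2 pi t / 24 h) + seasonal_amplitude *
#' sin(2 pi t / 365 d) + drift_slope * t`. Fluctuations are built from a
#' single standardized AR(1) chain with relaxation time `tau_true`
#' (coefficient `exp(-step / tau)`), carried across the whole record and
#' scaled within each epoch by `1 / sqrt(beta_epoch)`, so each epoch is
#' exactly a locally Gaussian process with stationary variance
#' `1 / beta_epoch` while the relaxation time is preserved globally.
#' Variance re-targeting at epoch boundaries is instantaneous.
#'
#' @param config A [synthetic_config()] list.
#' @return A list with `series` (a `superstat_ts` tibble) and `truth`
#'   (a list with `trend`, `fluctuations`, `epoch_id`, `beta_per_epoch`,
#'   `epoch_boundaries`).
#' @export
generate_superstat_series <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "superstat_config"))
  cf <- config
  n <- as.integer(round(cf$duration_days * 24 * 60 / cf$step_minutes))
  t_hours <- (seq_len(n) - 1) * cf$step_minutes / 60
  trend <- cf$daily_amplitude * sin(2 * pi * t_hours / 24) +
    cf$seasonal_amplitude * sin(2 * pi * t_hours / (365 * 24)) +
    cf$drift_slope * t_hours / 24

  epoch_len <- max(1L, as.integer(round(cf$T_true_hours * 60 /
                                          cf$step_minutes)))
  n_epochs <- ceiling(n / epoch_len)
  epoch_id <- rep(seq_len(n_epochs), each = epoch_len)[seq_len(n)]

  fluct <- withr::with_seed(cf$seed, {
    betas <- sample_beta(n_epochs, cf$beta_law, cf$beta_params)
    z <- if (cf$tau_true_hours <= 0) {
      rnorm(n)
    } else {
      phi <- exp(-(cf$step_minutes / 60) / cf$tau_true_hours)
      as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                               method = "recursive",
                               init = rnorm(1)))
    }
    list(z = z, betas = betas)
  })
  values <- trend + fluct$z / sqrt(fluct$betas[epoch_id])

  start <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  series <- new_superstat_ts(
    tibble::tibble(
      timestamp = start + (seq_len(n) - 1) * cf$step_minutes * 60,
      value = values
    ),
    parameter = "synthetic", site = "SIM"
  )
  truth <- list(
    trend = trend,
    fluctuations = values - trend,
    epoch_id = epoch_id,
    beta_per_epoch = fluct$betas,
    epoch_boundaries = (seq_len(n_epochs) - 1) * cf$T_true_hours,
    config = cf
  )
  list(series = series, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits the CSV dialect that [read_series()] reads, plus a ground-truth
#' JSON (config and per-epoch beta values) for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param csv_path Output CSV path.
#' @param truth_path Optional ground-truth JSON path.
#' @return The generated series, invisibly.
#' @export
write_synthetic_fixture <- function(config, csv_path, truth_path = NULL) {
  gen <- generate_superstat_series(config)
  write_series(gen$series, csv_path)
  if (!is.null(truth_path)) {
    cf <- gen$truth$config
    jsonlite::write_json(
      list(config = unclass(cf),
           beta_per_epoch = gen$truth$beta_per_epoch,
           epoch_boundaries_hours = gen$truth$epoch_boundaries),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(gen$series)
}
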