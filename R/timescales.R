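#' Short relaxation timescale from autocorrelation decay
#'
#' Estimates the relaxation time `tau` of a fluctuation process whose
#' autocorrelation decays approximately as `exp(-t / tau)`. The primary
#' estimate is the lag at which the empirical autocorrelation first falls
#' below `exp(-1)`, with linear interpolation between integer lags. As a
#' cross-check, a least-squares exponential fit (linear regression of
#' log-ACF on lag) over the lags before the first non-positive ACF value is
#' also reported.
#'
#' When the ACF is already below `exp(-1)` at lag 1 the decay is not
#' resolved by the sampling grid: `tau` is floored at one step and flagged.
#'
#' @param fluctuations Numeric vector (gaps `NA` are dropped pairwise by the
#'   ACF computation); length >= 100.
#' @param step_minutes Sampling step in minutes (default 15).
#' @param max_lag_hours Longest lag probed (default 48 h).
#'
#' @return A list of class `superstat_tau` with `tau_hours`,
#'   `tau_fit_hours` (exponential-fit cross-check), and
#'   `resolution_limited` flag.
#' @export
short_timescale <- function(fluctuations, step_minutes = 15,
                            max_lag_hours = 48) {
  x <- as.numeric(fluctuations)
  x <- x[!is.na(x)]
  if (length(x) < 100) {
    abort("need at least 100 samples for the autocorrelation",
          class = "superstat_param_error")
  }
  max_lag <- min(length(x) - 1L,
                 as.integer(round(max_lag_hours * 60 / step_minutes)))
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]   # drop lag 0
  target <- exp(-1)
  step_h <- step_minutes / 60

  if (rho[1] < target) {
    tau_hours <- step_h
    resolution_limited <- TRUE
  } else {
    below <- which(rho < target)
    if (length(below) == 0) {
      # never decays below 1/e within the probed range; report the range end
      tau_hours <- max_lag * step_h
      resolution_limited <- FALSE
    } else {
      k <- below[1]
      r_hi <- if (k == 1) 1 else rho[k - 1]
      frac <- (r_hi - target) / (r_hi - rho[k])
      tau_hours <- ((k - 1) + frac) * step_h
      resolution_limited <- FALSE
    }
  }

  # least-squares exponential fit over lags before the first zero crossing
  kmax <- which(rho <= 0)[1]
  kmax <- if (is.na(kmax)) length(rho) else kmax - 1L
  tau_fit_hours <- NA_real_
  if (kmax >= 2) {
    lags <- seq_len(kmax)
    fit <- stats::lm.fit(cbind(1, lags), log(rho[lags]))
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope < 0) tau_fit_hours <- -step_h / slope
  }

  structure(list(tau_hours = unname(tau_hours),
                 tau_fit_hours = unname(tau_fit_hours),
                 resolution_limited = resolution_limited),
            class = "superstat_tau")
}

#' Remove deterministic cyclic components by harmonic regression
#'
#' Least-squares fit of sine/cosine pairs at the given periods (plus an
#' intercept and optional linear drift), returning the residuals. Unlike a
#' moving average, subtracting a fitted deterministic harmonic does not
#' distort the autocorrelation of the stochastic component at any lag, which
#' makes this the right cycle-removal step before estimating the short
#' relaxation timescale.
#'
#' @param values Numeric series on a uniform grid (`NA` allowed).
#' @param step_minutes Sampling step in minutes.
#' @param periods_hours Cycle periods to remove (default: daily, half-daily
#'   harmonic, and annual).
#' @param drift Include a linear drift term (default `TRUE`).
#' @return Residual series, same length as `values`.
#' @export
remove_cycles <- function(values, step_minutes = 15,
                          periods_hours = c(24, 12, 365 * 24),
                          drift = TRUE) {
  n <- length(values)
  t_h <- (seq_len(n) - 1) * step_minutes / 60
  X <- cbind(1, if (drift) t_h)
  for (p in periods_hours) {
    X <- cbind(X, sin(2 * pi * t_h / p), cos(2 * pi * t_h / p))
  }
  ok <- !is.na(values)
  fit <- stats::lm.fit(X[ok, , drop = FALSE], values[ok])
  out <- rep(NA_real_, n)
  out[ok] <- fit$residuals
  out
}

#' Per-window inverse-variance (beta) extraction
#'
#' Partitions the fluctuation series into consecutive non-overlapping windows
#' of length `T_hours` and computes, for each complete window, the local
#' inverse variance `beta = 1 / s^2`, with `s^2` the population variance
#' about the window's own mean. Non-overlapping windows give approximately
#' independent beta draws for distribution fitting. Windows containing gap
#' markers or with zero variance are skipped (count recorded).
#'
#' @param fluctuations Numeric vector of detrended fluctuations.
#' @param T_hours Window length in hours (the long timescale).
#' @param step_minutes Sampling step in minutes (default 15).
#'
#' @return A tibble of class `superstat_betas` with columns `window`,
#'   `beta`, `window_mean`; attributes `samples_per_window`, `n_skipped`,
#'   `window_hours`.
#' @export
extract_betas <- function(fluctuations, T_hours, step_minutes = 15) {
  if (is.na(T_hours) || T_hours <= 0) {
    abort("T_hours must be a defined positive timescale",
          class = "superstat_param_error")
  }
  x <- as.numeric(fluctuations)
  w <- max(2L, as.integer(round(T_hours * 60 / step_minutes)))
  n_win <- length(x) %/% w
  if (n_win < 5) {
    abort("fewer than 5 complete windows of length T",
          class = "superstat_insufficient_error")
  }
  idx <- rep(seq_len(n_win), each = w)
  xs <- x[seq_len(n_win * w)]
  rows <- purrr::map(seq_len(n_win), function(k) {
    u <- xs[idx == k]
    if (anyNA(u)) return(NULL)
    m <- mean(u)
    v <- mean((u - m)^2)
    if (v <= 0) return(NULL)
    tibble::tibble(window = k, beta = 1 / v, window_mean = m)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < 5) {
    abort("fewer than 5 usable (gap-free, nonzero-variance) windows",
          class = "superstat_insufficient_error")
  }
  attr(out, "samples_per_window") <- w
  attr(out, "window_hours") <- T_hours
  attr(out, "n_skipped") <- n_win - nrow(out)
  class(out) <- c("superstat_betas", class(out))
  out
}

#' Timescale separation check
#'
#' The superstatistical description requires the relaxation time `tau` to be
#' much shorter than the parameter timescale `T` (`tau << T`). This reports
#' the ratio `tau / T` and whether it falls below `threshold`.
#'
#' @param T_hours Long timescale in hours (`NA` when undefined).
#' @param tau_hours Short timescale in hours.
#' @param threshold Pass level for the ratio (default 0.1).
#'
#' @return A one-row tibble with `tau_hours`, `T_hours`, `ratio`, `pass`,
#'   `applicable`.
#' @export
check_separation <- function(T_hours, tau_hours, threshold = 0.1) {
  if (is.na(T_hours)) {
    return(tibble::tibble(tau_hours = tau_hours, T_hours = NA_real_,
                          ratio = NA_real_, pass = NA,
                          applicable = FALSE))
  }
  ratio <- tau_hours / T_hours
  tibble::tibble(tau_hours = tau_hours, T_hours = T_hours, ratio = ratio,
                 pass = ratio < threshold, applicable = TRUE)
}
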