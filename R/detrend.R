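#' Seasonal detrending by centred moving average
#'
#' Splits a series additively into trend and fluctuations,
#' `value = trend + fluctuation`, where the trend is a centred moving average
#' with filtering window `f_hours`. For an even number of samples in the
#' window, the standard 2xMA treatment is used (the average of the two
#' offset even-length means, i.e. half weights at the window edges) so the
#' trend stays centred without phase shift. Endpoints where the full window
#' does not fit have an undefined trend (`NA`) and are excluded downstream.
#'
#' @param data A data frame with `timestamp` and `value` columns on a uniform
#'   grid, or a numeric vector of values.
#' @param f_hours Filtering window in hours (default 6).
#' @param step_minutes Sampling step in minutes; inferred from `timestamp`
#'   when `data` is a data frame.
#'
#' @return A tibble with columns `timestamp` (if available), `value`,
#'   `trend`, `fluctuation`, of class `superstat_decomposition`, carrying
#'   `method` and `params` attributes.
#' @export
seasonal_decompose <- function(data, f_hours = 6, step_minutes = NULL) {
  ts <- as_value_series(data, step_minutes)
  w <- round(f_hours * 60 / ts$step_minutes)
  if (w < 2) {
    abort("filtering window must cover at least 2 samples",
          class = "superstat_param_error")
  }
  if (w >= length(ts$value)) {
    abort("filtering window longer than the series",
          class = "superstat_empty_error")
  }
  trend <- centered_ma(ts$value, w)
  fluct <- ts$value - trend
  new_decomposition(ts, trend, fluct, method = "seasonal",
                    params = list(f_hours = f_hours))
}

# centred moving average; even windows use the 2xMA convention
# (weights 1/2, 1, ..., 1, 1/2 over w+1 points, scaled by 1/w)
centered_ma <- function(x, w) {
  if (w %% 2 == 1) {
    kernel <- rep(1 / w, w)
  } else {
    kernel <- c(0.5, rep(1, w - 1), 0.5) / w
  }
  as.numeric(stats::filter(x, kernel, method = "convolution", sides = 2))
}

new_decomposition <- function(ts, trend, fluct, method, params) {
  out <- tibble::tibble(value = ts$value, trend = trend, fluctuation = fluct)
  if (!is.null(ts$timestamp)) {
    out <- tibble::add_column(out, timestamp = ts$timestamp, .before = 1)
  }
  attr(out, "method") <- method
  attr(out, "params") <- params
  attr(out, "step_minutes") <- ts$step_minutes
  class(out) <- c("superstat_decomposition", class(out))
  out
}

# Normalize the user-facing 'data frame or numeric vector' input contract.
as_value_series <- function(data, step_minutes = NULL) {
  if (is.numeric(data)) {
    if (is.null(step_minutes)) step_minutes <- 15
    return(list(timestamp = NULL, value = as.numeric(data),
                step_minutes = step_minutes))
  }
  stopifnot(is.data.frame(data), "value" %in% names(data))
  step <- step_minutes %||% attr(data, "step_minutes") %||%
    infer_step_minutes(data$timestamp)
  if (is.null(step) || is.na(step)) {
    abort("cannot infer sampling step; pass step_minutes",
          class = "superstat_param_error")
  }
  list(timestamp = data[["timestamp"]], value = as.numeric(data$value),
       step_minutes = step)
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a gap-free series into intrinsic mode functions (IMFs) by the
#' standard sifting procedure: local extrema detection, natural cubic-spline
#' upper and lower envelopes on mirror-extended extrema, repeated
#' mean-envelope subtraction with a Cauchy-type stopping criterion, and a
#' final monotone residual. Modes are returned *slowest first* (residual
#' first, fastest oscillation last), so that the leading modes carry the
#' trend; the element-wise sum of all modes reconstructs the input exactly.
#'
#' @param data Data frame with a `value` column, or numeric vector; must be
#'   gap-free (no `NA`).
#' @param max_imfs Maximum number of oscillatory modes to extract.
#' @param sd_threshold Cauchy stopping threshold for the sifting loop
#'   (default 0.2).
#' @param max_sift Maximum sifting iterations per mode (default 12).
#'
#' @return An object of class `superstat_imfset`: a list with `modes` (a
#'   list of numeric vectors, slowest first), `n_modes`, and `sift_meta`.
#' @export
emd <- function(data, max_imfs = 12L, sd_threshold = 0.2, max_sift = 12L) {
  ts <- as_value_series(data)
  x <- ts$value
  if (anyNA(x)) {
    abort("emd requires a gap-free series", class = "superstat_param_error")
  }
  if (length(x) < 16) {
    abort("series too short for EMD (need >= 16 samples)",
          class = "superstat_param_error")
  }
  residual <- x
  imfs <- list()
  sift_counts <- integer()
  for (k in seq_len(max_imfs)) {
    ext <- find_extrema(residual)
    if (length(ext$maxima) + length(ext$minima) < 2 ||
        length(ext$maxima) < 1 || length(ext$minima) < 1) break
    h <- residual
    n_sift <- 0L
    repeat {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      n_sift <- n_sift + 1L
      sd_k <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_k < sd_threshold || n_sift >= max_sift) break
    }
    imfs[[length(imfs) + 1L]] <- h
    sift_counts <- c(sift_counts, n_sift)
    residual <- residual - h
  }
  # slowest first: residual, then IMFs from last-extracted (slowest) to first
  modes <- c(list(residual), rev(imfs))
  structure(
    list(modes = modes, n_modes = length(modes),
         sift_meta = list(sd_threshold = sd_threshold,
                          max_sift = max_sift,
                          sift_counts = rev(sift_counts)),
         timestamp = ts$timestamp, value = x,
         step_minutes = ts$step_minutes),
    class = "superstat_imfset"
  )
}

#' @export
print.superstat_imfset <- function(x, ...) {
  cat("<superstat_imfset> ", x$n_modes, " modes over ",
      length(x$value), " samples (slowest first)\n", sep = "")
  invisible(x)
}

# indices of strict local maxima and minima; plateaus are collapsed to their
# midpoint sample
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(), minima = integer()))
  d <- diff(x)
  s <- sign(d)
  # carry the sign through flat segments so plateaus register once
  for (i in seq_along(s)) {
    if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  }
  ds <- diff(s)
  maxima <- which(ds < 0) + 1L
  minima <- which(ds > 0) + 1L
  list(maxima = maxima, minima = minima)
}

# mean of the upper/lower cubic-spline envelopes with mirror-symmetric
# extension of up to 2 boundary extrema at each end; NULL when envelopes
# cannot be formed
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$maxima) < 1 || length(ext$minima) < 1) return(NULL)
  up <- spline_envelope(ext$maxima, x, n)
  lo <- spline_envelope(ext$minima, x, n)
  (up + lo) / 2
}

spline_envelope <- function(idx, x, n) {
  t <- as.numeric(idx)
  v <- x[idx]
  # mirror up to 2 extrema across each boundary
  kl <- seq_len(min(2L, length(t)))
  kr <- seq(length(t), by = -1L, length.out = min(2L, length(t)))
  t_ext <- c(2 - rev(t[kl]), t, 2 * n - t[kr])
  v_ext <- c(rev(v[kl]), v, v[kr])
  keep <- !duplicated(t_ext)
  f <- splinefun(t_ext[keep], v_ext[keep], method = "natural")
  f(seq_len(n))
}

#' Partition EMD modes into trend and fluctuations
#'
#' Keeps the first `n_modes - m` (slowest) modes as the trend and sums the
#' last `m` (fastest) modes into the fluctuation component, preserving the
#' additive identity trend + fluctuation = input.
#'
#' @param imfs A `superstat_imfset` from [emd()].
#' @param m Number of fast modes attributed to the fluctuations (default 2).
#'
#' @return A `superstat_decomposition` tibble as from [seasonal_decompose()].
#' @export
partition_modes <- function(imfs, m = 2L) {
  stopifnot(inherits(imfs, "superstat_imfset"))
  N <- imfs$n_modes
  if (m < 0 || m > N) {
    abort(paste0("m must be in [0, ", N, "]"),
          class = "superstat_param_error")
  }
  zero <- rep(0, length(imfs$value))
  trend <- Reduce(`+`, imfs$modes[seq_len(N - m)], accumulate = FALSE,
                  init = zero)
  fluct <- imfs$value - trend
  ts <- list(timestamp = imfs$timestamp, value = imfs$value,
             step_minutes = imfs$step_minutes)
  new_decomposition(ts, trend, fluct, method = "emd",
                    params = list(m = m, n_modes = N))
}

#' Detrend a series with either method
#'
#' Convenience wrapper dispatching to [seasonal_decompose()] or
#' [emd()] + [partition_modes()].
#'
#' @param data Data frame with `timestamp`/`value` or numeric vector.
#' @param method `"seasonal"` or `"emd"`.
#' @param f_hours Filtering window for the seasonal method (hours).
#' @param m Fluctuation mode count for the EMD method.
#' @param ... Passed to the underlying method.
#' @return A `superstat_decomposition` tibble.
#' @export
detrend <- function(data, method = c("seasonal", "emd"), f_hours = 6,
                    m = 2L, ...) {
  method <- match.arg(method)
  if (method == "seasonal") {
    seasonal_decompose(data, f_hours = f_hours, ...)
  } else {
    partition_modes(emd(data, ...), m = m)
  }
}
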