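#' Read a sensor time series from CSV
#'
#' Reads a delimited text file with a timestamp column (ISO-8601) and a value
#' column into a tidy time-series tibble. Rows are sorted by time and duplicate
#' timestamps are collapsed by their mean (sensor re-transmissions), with a
#' warning giving the number collapsed.
#'
#' @param path Path to a CSV file with a header row.
#' @param timestamp_column,value_column Names of the timestamp and value
#'   columns in the file.
#' @param parameter Label for the measured quantity, with units
#'   (e.g. `"dissolved_oxygen mg/L"`).
#' @param site Site label (e.g. `"LC"`).
#'
#' @return A tibble with columns `timestamp` (POSIXct, UTC-naive local time)
#'   and `value`, of class `superstat_ts`, carrying `parameter`, `site` and
#'   `step_minutes` attributes.
#' @export
read_series <- function(path, timestamp_column = "timestamp",
                        value_column = "value",
                        parameter = NA_character_, site = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "superstat_config_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(timestamp_column, value_column)) {
    if (!col %in% names(raw)) {
      abort(paste0("column '", col, "' not present in ", path),
            class = "superstat_config_error")
    }
  }
  ts <- as.POSIXct(raw[[timestamp_column]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  val <- as.numeric(raw[[value_column]])
  keep <- !is.na(ts)
  if (!any(keep)) {
    abort("no parseable timestamps in input", class = "superstat_empty_error")
  }
  out <- tibble::tibble(timestamp = ts[keep], value = val[keep]) |>
    dplyr::arrange(.data$timestamp)
  ndup <- sum(duplicated(out$timestamp))
  if (ndup > 0) {
    warn(paste0("collapsed ", ndup, " duplicate timestamp(s) by mean"))
    out <- out |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .by = "timestamp")
  }
  new_superstat_ts(out, parameter = parameter, site = site)
}

new_superstat_ts <- function(data, parameter = NA_character_,
                             site = NA_character_, gap_report = NULL) {
  stopifnot(all(c("timestamp", "value") %in% names(data)))
  out <- tibble::as_tibble(data)
  attr(out, "parameter") <- parameter
  attr(out, "site") <- site
  attr(out, "step_minutes") <- infer_step_minutes(out$timestamp)
  if (!is.null(gap_report)) attr(out, "gap_report") <- gap_report
  class(out) <- c("superstat_ts", class(out))
  out
}

#' Infer the sampling step of a timestamp vector, in minutes
#'
#' @param timestamps POSIXct vector, strictly increasing.
#' @return The median spacing in minutes.
#' @export
infer_step_minutes <- function(timestamps) {
  if (length(timestamps) < 2) return(NA_real_)
  as.numeric(median(diff(as.numeric(timestamps)))) / 60
}

#' Regularize a time series onto a uniform grid
#'
#' Places the series on a uniform grid of spacing `step_minutes` anchored at
#' the first timestamp. Gaps of at most `max_gap_minutes` are filled by linear
#' interpolation; longer gaps are kept as `NA` gap markers so that analysis
#' windows overlapping them can be excluded downstream. A gap report
#' (interpolated and missing counts) is attached as an attribute and returned
#' invisibly in the tibble.
#'
#' @param data A data frame with `timestamp` and `value` columns.
#' @param step_minutes Target grid spacing in minutes (default 15).
#' @param max_gap_minutes Longest gap to bridge by interpolation (default 60).
#'
#' @return A `superstat_ts` tibble on the uniform grid, with a `gap_report`
#'   attribute listing `n_interpolated` and `n_missing`.
#' @export
regularize <- function(data, step_minutes = 15, max_gap_minutes = 60) {
  stopifnot(step_minutes > 0)
  if (nrow(data) == 0) {
    abort("empty series", class = "superstat_empty_error")
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$timestamp)
  t0 <- as.numeric(data$timestamp[1])
  tn <- as.numeric(data$timestamp[nrow(data)])
  step_s <- step_minutes * 60
  grid <- seq(t0, tn, by = step_s)
  obs_t <- as.numeric(data$timestamp)
  obs_v <- data$value
  # snap observations to the nearest grid point when within half a step
  idx <- round((obs_t - t0) / step_s) + 1
  on_grid <- abs(obs_t - (t0 + (idx - 1) * step_s)) < step_s / 2 &
    idx >= 1 & idx <= length(grid)
  vals <- rep(NA_real_, length(grid))
  vals[idx[on_grid]] <- obs_v[on_grid]

  missing_before <- is.na(vals)
  if (all(missing_before)) {
    abort("regularization produced an all-gap series",
          class = "superstat_empty_error")
  }
  filled <- fill_short_gaps(vals, max_gap_steps = max_gap_minutes / step_minutes)
  gap_report <- list(
    n_interpolated = sum(missing_before & !is.na(filled)),
    n_missing = sum(is.na(filled)),
    step_minutes = step_minutes,
    max_gap_minutes = max_gap_minutes
  )
  out <- tibble::tibble(
    timestamp = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
    value = filled
  )
  new_superstat_ts(out, parameter = attr(data, "parameter"),
                   site = attr(data, "site"), gap_report = gap_report)
}

# linear interpolation of NA runs no longer than max_gap_steps; longer runs
# stay NA. Never touches non-NA entries.
fill_short_gaps <- function(x, max_gap_steps) {
  nas <- is.na(x)
  if (!any(nas)) return(x)
  r <- rle(nas)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- x
  obs_idx <- which(!nas)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (r$lengths[k] > max_gap_steps) next
    lo <- starts[k] - 1
    hi <- ends[k] + 1
    if (lo < 1 || hi > length(x)) next   # boundary gaps are not extrapolated
    seg <- starts[k]:ends[k]
    out[seg] <- x[lo] + (x[hi] - x[lo]) * (seg - lo) / (hi - lo)
  }
  out
}

#' Write a time series and its metadata sidecar
#'
#' Writes a two-column CSV (`timestamp`, `value`) and, optionally, a JSON
#' sidecar with site, parameter, step and gap-report metadata, so that
#' `read_series()` round-trips the payload.
#'
#' @param data A data frame with `timestamp` and `value` columns.
#' @param path Output CSV path.
#' @param meta_path Optional path for the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(data, path, meta_path = NULL) {
  out <- data.frame(
    timestamp = format(data$timestamp, "%Y-%m-%dT%H:%M:%S"),
    value = data$value
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(
      site = attr(data, "site") %||% NA_character_,
      parameter = attr(data, "parameter") %||% NA_character_,
      step_minutes = attr(data, "step_minutes") %||%
        infer_step_minutes(data$timestamp),
      gap_report = attr(data, "gap_report")
    )
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}
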