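# fixtures are generated in code; no binary data on disk

# wrap a numeric vector as a timestamped series tibble (step in minutes)
make_ts <- function(values, step_minutes = 15,
                    start = as.POSIXct("2019-06-01", tz = "UTC")) {
  tibble::tibble(
    timestamp = start + (seq_along(values) - 1) * step_minutes * 60,
    value = values
  )
}

# stationary AR(1) noise with relaxation time tau (hours) at the given step
ou_series <- function(n, tau_hours = 1, step_minutes = 15, sd = 1,
                      seed = 1) {
  withr::with_seed(seed, {
    phi <- exp(-(step_minutes / 60) / tau_hours)
    as.numeric(stats::filter(rnorm(n, sd = sd * sqrt(1 - phi^2)), phi,
                             method = "recursive", init = rnorm(1, sd = sd)))
  })
}

# write a small CSV fixture and return its path
write_csv_fixture <- function(df, dir = withr::local_tempdir(.local_envir =
                                                               parent.frame())) {
  path <- file.path(dir, "series.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
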