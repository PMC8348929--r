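#' Plot a trend/fluctuation decomposition
#'
#' @param object A `superstat_decomposition` tibble.
#' @param ... Unused.
#' @return A ggplot object: original series with the trend overlaid, and the
#'   fluctuation component below.
#' @exportS3Method ggplot2::autoplot
autoplot.superstat_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"timestamp" %in% names(df)) {
    df$timestamp <- seq_len(nrow(df))
  }
  long <- df |>
    tidyr::pivot_longer(c("value", "trend", "fluctuation"),
                        names_to = "component", values_to = "y") |>
    dplyr::mutate(panel = ifelse(.data$component == "fluctuation",
                                 "fluctuations", "series + trend"))
  ggplot2::ggplot(long, ggplot2::aes(.data$timestamp, .data$y,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Additive decomposition (",
                                 attr(object, "method"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the average-kurtosis curve
#'
#' @param object A `superstat_kurtosis_curve` tibble.
#' @param kappa_target Crossing level to mark (default 3).
#' @param ... Unused.
#' @return A ggplot object with the Gaussian level and, when defined, the
#'   extracted long timescale marked.
#' @exportS3Method ggplot2::autoplot
autoplot.superstat_kurtosis_curve <- function(object, kappa_target = 3, ...) {
  Th <- long_timescale(object, kappa_target = kappa_target)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$window_hours, .data$kappa_bar)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = kappa_target, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(Delta * t ~ "(hours)"),
                  y = expression(bar(kappa)),
                  title = "Average kurtosis vs window size") +
    ggplot2::theme_minimal()
  if (!is.na(Th)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(Th),
                                 linetype = "dotted")
  }
  p
}

#' Plot the empirical beta-distribution with fitted candidate laws
#'
#' @param object A `superstat_betas` tibble from [extract_betas()].
#' @param fits Optional `superstat_fit_comparison` whose fitted densities
#'   are overlaid.
#' @param ... Unused.
#' @return A ggplot object: Gaussian-kernel estimate of the empirical beta
#'   PDF with fitted density curves.
#' @exportS3Method ggplot2::autoplot
autoplot.superstat_betas <- function(object, fits = NULL, ...) {
  b <- object$beta
  grid <- seq(max(min(b) / 2, 1e-8), quantile(b, 0.995) * 1.3,
              length.out = 400)
  df <- tibble::tibble(beta = grid,
                       density = kde_pdf(b, grid),
                       curve = "empirical (KDE)")
  if (!is.null(fits)) {
    fit_df <- purrr::map(fits$fit, function(f) {
      if (length(f$params) == 0) return(NULL)
      tibble::tibble(beta = grid,
                     density = beta_pdf(grid, f$family, f$params),
                     curve = f$family)
    }) |> dplyr::bind_rows()
    df <- dplyr::bind_rows(df, fit_df)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$density,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta), y = "density",
                  title = "Beta-distribution with fitted candidate laws") +
    ggplot2::theme_minimal()
}

#' Plot fluctuation marginal with a fitted q-Gaussian
#'
#' @param fluctuations Numeric fluctuation sample.
#' @param fit Optional `superstat_fit` from [fit_qgaussian()]; fitted on the
#'   fly when omitted.
#' @return A ggplot object on a log density scale (heavy tails visible).
#' @export
plot_qgaussian_fit <- function(fluctuations, fit = NULL) {
  x <- fluctuations[!is.na(fluctuations)]
  if (is.null(fit)) fit <- fit_qgaussian(x)
  grid <- seq(quantile(x, 0.0005), quantile(x, 0.9995), length.out = 400)
  df <- dplyr::bind_rows(
    tibble::tibble(x = grid, density = kde_pdf(x, grid),
                   curve = "empirical (KDE)"),
    tibble::tibble(x = grid,
                   density = qgaussian_pdf(grid, fit$params$q, fit$params$b,
                                           fit$params$mu),
                   curve = sprintf("q-Gaussian (q = %.2f)", fit$params$q))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fluctuation", y = "density (log scale)",
                  title = "Fluctuation marginal and q-Gaussian fit") +
    ggplot2::theme_minimal()
}
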