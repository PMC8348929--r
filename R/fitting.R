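new_fit_result <- function(family, params, loglik, n_obs, converged,
                           fit_meta = list()) {
  k <- length(params)
  structure(
    list(family = family, params = params, loglik = loglik,
         aic = 2 * k - 2 * loglik, n_params = k, n_obs = n_obs,
         converged = converged, fit_meta = fit_meta),
    class = "superstat_fit"
  )
}

#' @export
print.superstat_fit <- function(x, ...) {
  cat("<superstat_fit> family:", x$family,
      if (!x$converged) "(NOT converged)", "\n")
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 5), sep = " = ",
                         collapse = ", "), "\n")
  cat("  loglik:", signif(x$loglik, 8), "  AIC:", signif(x$aic, 8),
      "  n:", x$n_obs, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.superstat_fit <- function(x, ...) {
  tibble::tibble(family = x$family, term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @exportS3Method generics::glance
glance.superstat_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
                 nobs = x$n_obs, converged = x$converged)
}

#' Maximum-likelihood fit of a single beta-distribution family
#'
#' Fits one candidate law to a sample of beta values. The log-normal fit is
#' closed form (sample mean and 1/n standard deviation of `log beta`); the
#' chi-squared and inverse chi-squared fits maximize the likelihood
#' numerically in `(log n, log beta0)` from moment-matched starting values.
#'
#' @param betas Positive numeric sample (either a plain vector or the
#'   `superstat_betas` tibble from [extract_betas()]); at least 5 values.
#' @param family `"chi2"`, `"inv_chi2"` or `"lognormal"` (for the mixture
#'   use [fit_chi2_mixture()]).
#' @return A `superstat_fit` object with `params`, `loglik` and `aic`.
#' @export
fit_beta_family <- function(betas, family = c("chi2", "inv_chi2",
                                              "lognormal")) {
  family <- match.arg(family)
  b <- betas_vector(betas)
  if (any(b <= 0)) {
    abort("beta values must be positive", class = "superstat_domain_error")
  }
  if (length(b) < 5) {
    abort("need at least 5 beta values", class = "superstat_param_error")
  }
  n_obs <- length(b)

  if (family == "lognormal") {
    lb <- log(b)
    mu <- mean(lb)
    sg <- sqrt(mean((lb - mu)^2))
    if (sg <= 0) {
      abort("zero log-variance: log-normal fit degenerate",
            class = "superstat_degenerate_error")
    }
    ll <- sum(dlnorm(b, mu, sg, log = TRUE))
    return(new_fit_result("lognormal", list(mu_ln = mu, sigma_ln = sg),
                          ll, n_obs, TRUE))
  }

  y <- if (family == "chi2") b else 1 / b
  # moment-matched gamma start for y ~ gamma(shape n/2, ...)
  a0 <- max(0.05, mean(y)^2 / max(var(y), .Machine$double.eps))
  start <- switch(family,
                  chi2 = c(log(2 * a0), log(mean(b))),
                  inv_chi2 = c(log(2 * a0), log(1 / mean(y))))
  negll <- function(theta) {
    n <- exp(theta[1]); beta0 <- exp(theta[2])
    if (!is.finite(n) || !is.finite(beta0)) return(1e10)
    ll <- sum(beta_pdf(b, family, list(n = n, beta0 = beta0), log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(start, negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  params <- list(n = exp(opt$par[1]), beta0 = exp(opt$par[2]))
  new_fit_result(family, params, -opt$value, n_obs,
                 converged = opt$convergence == 0,
                 fit_meta = list(start = start, counts = opt$counts))
}

betas_vector <- function(betas) {
  if (is.data.frame(betas)) as.numeric(betas$beta) else as.numeric(betas)
}

#' Maximum-likelihood q-Gaussian fit
#'
#' Fits the q-Gaussian `(q, b, mu)` to a fluctuation sample by numerical
#' likelihood maximization, with multiple starts over
#' `q in {1.05, 1.3, 1.6, 2.0}`, `mu` started at the sample median and `b`
#' moment-matched (for `q < 5/3` the variance is `1 / (b (5 - 3 q))`).
#' `q` is constrained to `[1, 2.8]`.
#'
#' @param samples Numeric sample, at least 100 values.
#' @param q_starts Starting values for `q`.
#' @return A `superstat_fit` with params `q`, `b`, `mu`.
#' @export
fit_qgaussian <- function(samples, q_starts = c(1.05, 1.3, 1.6, 2.0)) {
  x <- samples[!is.na(samples)]
  if (length(x) < 100) {
    abort("need at least 100 samples", class = "superstat_param_error")
  }
  mu0 <- median(x)
  v <- var(x)
  robust_v <- mad(x)^2
  negll <- function(theta) {
    q <- theta[1]; b <- exp(theta[2]); mu <- theta[3]
    if (q < 1 || q >= 2.8 || !is.finite(b)) return(1e10)
    ll <- sum(qgaussian_pdf(x, q, b, mu, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (q0 in q_starts) {
    b0 <- if (q0 < 5 / 3) 1 / (v * (5 - 3 * q0)) else 1 / (2 * robust_v)
    if (!is.finite(b0) || b0 <= 0) b0 <- 1
    opt <- tryCatch(
      optim(c(q0, log(b0), mu0), negll, method = "L-BFGS-B",
            lower = c(1, -30, -Inf), upper = c(2.8, 30, Inf),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_fit_result("qgaussian", list(q = NA_real_, b = NA_real_,
                                            mu = NA_real_),
                          -Inf, length(x), FALSE))
  }
  params <- list(q = best$par[1], b = exp(best$par[2]), mu = best$par[3])
  new_fit_result("qgaussian", params, -best$value, length(x),
                 converged = best$convergence == 0,
                 fit_meta = list(q_starts = q_starts))
}

#' Fit the two-component chi-squared mixture by EM
#'
#' Maximum-likelihood estimation of `(W, n1, n2, beta0)` in the shared-scale
#' mixture of two chi-squared (gamma) beta-laws, by expectation-maximization
#' over component responsibilities. The M-step handles the shared `beta0`
#' constraint by nested one-dimensional optimization: an outer golden-section
#' search over `log beta0`, with each component's degrees of freedom profiled
#' out by an inner one-dimensional search (all on sufficient statistics, so
#' the M-step cost is independent of sample size). Multiple starts combine
#' `W in {0.2, 0.5, 0.8}` with quantile-split moment-matched shape pairs;
#' label switching is resolved by enforcing `n1 <= n2`.
#'
#' @param betas Positive sample (vector or `superstat_betas` tibble); at
#'   least 30 values.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `superstat_fit` with params `W`, `n1`, `n2`, `beta0`.
#' @export
fit_chi2_mixture <- function(betas, max_iter = 1000, tol = 1e-8) {
  b <- betas_vector(betas)
  if (any(b <= 0)) {
    abort("beta values must be positive", class = "superstat_domain_error")
  }
  if (length(b) < 30) {
    abort("need at least 30 beta values", class = "superstat_param_error")
  }
  n_obs <- length(b)
  lb <- log(b)
  beta0_hat <- mean(b)

  # shape from moment matching a gamma with mean beta0 to a subsample
  mm_shape <- function(sub) {
    v <- var(sub)
    if (!is.finite(v) || v <= 0) return(2)
    min(500, max(0.05, mean(sub)^2 / v))
  }
  splits <- list(
    quantile(b, 0.5), quantile(b, 0.25), quantile(b, 0.75)
  )
  shape_pairs <- purrr::map(splits, function(s) {
    lo <- b[b <= s]; hi <- b[b > s]
    if (length(lo) < 3 || length(hi) < 3) return(c(0.5, 10))
    sort(c(mm_shape(lo), mm_shape(hi)))
  })
  # the degenerate point n1 = n2 at the single-law MLE guarantees the
  # mixture likelihood nests the single chi-squared fit
  single <- fit_beta_family(b, "chi2")
  starts <- list(
    list(W = 0.2, a = shape_pairs[[1]]),
    list(W = 0.5, a = shape_pairs[[1]]),
    list(W = 0.8, a = shape_pairs[[1]]),
    list(W = 0.5, a = shape_pairs[[2]]),
    list(W = 0.5, a = shape_pairs[[3]])
  )

  obs_ll <- function(W, a1, a2, beta0) {
    sum(chi2_mixture_pdf(b, W, 2 * a1, 2 * a2, beta0, log = TRUE))
  }
  # expected complete-data log-lik contribution of one component from
  # sufficient statistics R = sum r, S = sum r*log(beta), M = sum r*beta
  comp_obj <- function(a, beta0, R, S, M) {
    R * (a * log(a / beta0) - lgamma(a)) + (a - 1) * S - a * M / beta0
  }
  best <- NULL
  for (st in starts) {
    W <- st$W; a1 <- st$a[1]; a2 <- st$a[2]; beta0 <- beta0_hat
    ll_old <- -Inf; ok <- FALSE
    for (it in seq_len(max_iter)) {
      l1 <- log(W) + dgamma(b, a1, rate = a1 / beta0, log = TRUE)
      l2 <- log1p(-W) + dgamma(b, a2, rate = a2 / beta0, log = TRUE)
      m <- pmax(l1, l2)
      ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
      r1 <- 1 / (1 + exp(l2 - l1))
      W <- mean(r1)
      W <- min(max(W, 1e-6), 1 - 1e-6)
      R1 <- sum(r1); S1 <- sum(r1 * lb); M1 <- sum(r1 * b)
      R2 <- n_obs - R1; S2 <- sum(lb) - S1; M2 <- sum(b) - M1
      prof <- function(lbeta0) {
        b0 <- exp(lbeta0)
        o1 <- optimize(function(la) -comp_obj(exp(la), b0, R1, S1, M1),
                       lower = log(0.025), upper = log(500))
        o2 <- optimize(function(la) -comp_obj(exp(la), b0, R2, S2, M2),
                       lower = log(0.025), upper = log(500))
        o1$objective + o2$objective
      }
      o0 <- optimize(prof, lower = log(beta0_hat / 50),
                     upper = log(beta0_hat * 50))
      beta0 <- exp(o0$minimum)
      a1 <- exp(optimize(function(la) -comp_obj(exp(la), beta0, R1, S1, M1),
                         lower = log(0.025), upper = log(500))$minimum)
      a2 <- exp(optimize(function(la) -comp_obj(exp(la), beta0, R2, S2, M2),
                         lower = log(0.025), upper = log(500))$minimum)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
        ok <- TRUE
        break
      }
      ll_old <- ll
    }
    ll_final <- obs_ll(W, a1, a2, beta0)
    cand <- list(W = W, a1 = a1, a2 = a2, beta0 = beta0, ll = ll_final,
                 converged = ok)
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }
  if (best$ll < single$loglik) {
    best <- list(W = 0.5, a1 = single$params$n / 2, a2 = single$params$n / 2,
                 beta0 = single$params$beta0, ll = single$loglik,
                 converged = single$converged)
  }
  # canonical labelling: component 1 has the smaller degrees of freedom
  if (best$a1 > best$a2) {
    best <- list(W = 1 - best$W, a1 = best$a2, a2 = best$a1,
                 beta0 = best$beta0, ll = best$ll,
                 converged = best$converged)
  }
  new_fit_result("chi2_mixture",
                 list(W = best$W, n1 = 2 * best$a1, n2 = 2 * best$a2,
                      beta0 = best$beta0),
                 best$ll, n_obs, best$converged,
                 fit_meta = list(n_starts = length(starts)))
}

#' Fit and rank all candidate beta-distribution families
#'
#' Fits each requested family to the same beta sample and ranks the fits by
#' AIC (ascending). A family whose fitter errors is kept in the table,
#' flagged, and ranked last.
#'
#' @param betas Positive sample (vector or `superstat_betas` tibble).
#' @param families Character vector from `"chi2"`, `"inv_chi2"`,
#'   `"lognormal"`, `"chi2_mixture"`.
#' @param seed Optional integer seed recorded with the comparison (the
#'   fitters themselves are deterministic given the data).
#' @return A tibble of class `superstat_fit_comparison` with columns
#'   `family`, `logLik`, `AIC`, `converged`, `rank`, and a `fit` list-column
#'   holding the full `superstat_fit` objects.
#' @export
compare_fits <- function(betas,
                         families = c("chi2", "inv_chi2", "lognormal",
                                      "chi2_mixture"),
                         seed = NULL) {
  b <- betas_vector(betas)
  if (length(b) < 30) {
    abort("need at least 30 beta values", class = "superstat_param_error")
  }
  fits <- purrr::map(families, function(fam) {
    tryCatch({
      if (fam == "chi2_mixture") fit_chi2_mixture(b)
      else fit_beta_family(b, fam)
    }, error = function(e) {
      new_fit_result(fam, list(), loglik = -Inf, n_obs = length(b),
                     converged = FALSE,
                     fit_meta = list(error = conditionMessage(e)))
    })
  })
  out <- purrr::map2(families, fits, function(fam, f) {
    tibble::tibble(family = fam, logLik = f$loglik, AIC = f$aic,
                   converged = f$converged, fit = list(f))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(is.finite(.data$AIC)), .data$AIC) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "seed") <- seed
  class(out) <- c("superstat_fit_comparison", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.superstat_fit_comparison <- function(x, ...) {
  purrr::map(x$fit, tidy) |> dplyr::bind_rows()
}

#' @exportS3Method generics::glance
glance.superstat_fit_comparison <- function(x, ...) {
  tibble::tibble(best_family = x$family[1], best_AIC = x$AIC[1],
                 n_families = nrow(x))
}
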