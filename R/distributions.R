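#' Candidate beta-distribution densities
#'
#' Densities for the inverse-variance parameter beta under the candidate
#' superstatistical laws:
#'
#' * `"chi2"`: the chi-squared form, a gamma density with shape `n/2` and
#'   mean `beta0` (rate `n / (2 beta0)`); `n` is the (possibly non-integer)
#'   degrees of freedom and `beta0` the mean of beta.
#' * `"inv_chi2"`: the inverse chi-squared form, `1/beta ~` gamma with shape
#'   `n/2` and rate `n beta0 / 2` (so `E[1/beta] = 1/beta0`); `beta0` acts
#'   as a scale.
#' * `"lognormal"`: `log beta ~ N(mu_ln, sigma_ln^2)`.
#'
#' @param beta Positive evaluation points.
#' @param family One of `"chi2"`, `"inv_chi2"`, `"lognormal"`,
#'   `"chi2_mixture"`.
#' @param params Named list of parameters for the family: `n`, `beta0` for
#'   the chi-squared forms; `mu_ln`, `sigma_ln` for the log-normal;
#'   `W`, `n1`, `n2`, `beta0` for the mixture.
#' @param log Return the log-density?
#' @return Density values (nonnegative), same length as `beta`.
#' @export
beta_pdf <- function(beta, family, params, log = FALSE) {
  if (any(beta <= 0)) {
    abort("beta must be positive", class = "superstat_domain_error")
  }
  switch(
    family,
    chi2 = dbeta_chi2(beta, params$n, params$beta0, log = log),
    inv_chi2 = dbeta_invchi2(beta, params$n, params$beta0, log = log),
    lognormal = dlnorm(beta, params$mu_ln, params$sigma_ln, log = log),
    chi2_mixture = chi2_mixture_pdf(beta, params$W, params$n1, params$n2,
                                    params$beta0, log = log),
    abort(paste0("unknown beta-distribution family: ", family),
          class = "superstat_config_error")
  )
}

#' @rdname beta_pdf
#' @param n Degrees of freedom (> 0, non-integer allowed).
#' @param beta0 Mean (chi-squared) or scale (inverse chi-squared) parameter.
#' @export
dbeta_chi2 <- function(beta, n, beta0, log = FALSE) {
  stopifnot(n > 0, beta0 > 0)
  dgamma(beta, shape = n / 2, rate = n / (2 * beta0), log = log)
}

#' @rdname beta_pdf
#' @export
dbeta_invchi2 <- function(beta, n, beta0, log = FALSE) {
  stopifnot(n > 0, beta0 > 0)
  # density of beta when 1/beta ~ gamma(shape n/2, rate n*beta0/2)
  ld <- dgamma(1 / beta, shape = n / 2, rate = n * beta0 / 2, log = TRUE) -
    2 * log(beta)
  if (log) ld else exp(ld)
}

#' Samplers for the candidate beta laws
#'
#' Draws i.i.d. beta values from one of the candidate laws; the chi-squared
#' form samples via the gamma distribution, the mixture via a component
#' indicator followed by the component gamma.
#'
#' @inheritParams beta_pdf
#' @param size Number of draws (>= 1).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the global RNG state is left untouched.
#' @return Numeric vector of positive draws.
#' @export
sample_beta <- function(size, family, params, seed = NULL) {
  if (!is.numeric(size) || size < 1) {
    abort("size must be >= 1", class = "superstat_config_error")
  }
  draw <- function() {
    switch(
      family,
      fixed = rep(params$beta, size),
      chi2 = rgamma(size, shape = params$n / 2,
                    rate = params$n / (2 * params$beta0)),
      inv_chi2 = 1 / rgamma(size, shape = params$n / 2,
                            rate = params$n * params$beta0 / 2),
      lognormal = rlnorm(size, params$mu_ln, params$sigma_ln),
      chi2_mixture = {
        comp <- rbinom(size, 1, params$W)
        nvec <- ifelse(comp == 1, params$n1, params$n2)
        rgamma(size, shape = nvec / 2, rate = nvec / (2 * params$beta0))
      },
      abort(paste0("unknown beta law: ", family),
            class = "superstat_config_error")
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Two-component chi-squared mixture density for beta
#'
#' The mixture `W * f_chi2(beta; n1, beta0) + (1 - W) * f_chi2(beta; n2,
#' beta0)`: two chi-squared (gamma) components sharing the scale `beta0`
#' (each component has mean `beta0`) but with their own degrees of freedom.
#' With one small (`n < 2`) and one large `n` this produces the double-peaked
#' beta-distributions seen in conductivity fluctuations: a peak adjacent to
#' zero and an interior peak near `beta0`.
#'
#' @param beta Positive evaluation points.
#' @param W Mixture weight in `[0, 1]` of the first component.
#' @param n1,n2 Degrees of freedom of the two components (> 0).
#' @param beta0 Shared scale (mean of each component).
#' @param log Return the log-density?
#' @return Density values.
#' @export
chi2_mixture_pdf <- function(beta, W, n1, n2, beta0, log = FALSE) {
  if (any(beta <= 0)) {
    abort("beta must be positive", class = "superstat_domain_error")
  }
  stopifnot(W >= 0, W <= 1, n1 > 0, n2 > 0, beta0 > 0)
  l1 <- dbeta_chi2(beta, n1, beta0, log = TRUE)
  l2 <- dbeta_chi2(beta, n2, beta0, log = TRUE)
  # log-sum-exp for numerical stability in the tails
  if (W == 0) ld <- l2
  else if (W == 1) ld <- l1
  else {
    a <- pmax(l1 + log(W), l2 + log1p(-W))
    b <- pmin(l1 + log(W), l2 + log1p(-W))
    ld <- a + log1p(exp(b - a))
  }
  if (log) ld else exp(ld)
}

#' q-Gaussian density
#'
#' The q-Gaussian density
#' `p(x) = sqrt(b) / C_q * (1 + (q - 1) b (x - mu)^2)^(1 / (1 - q))`,
#' normalized in closed form through gamma functions; it is symmetric about
#' `mu`, heavy-tailed for `q > 1`, and converges to the Gaussian with
#' variance `1 / (2 b)` as `q -> 1`. Normalizable for `1 <= q < 3`.
#'
#' @param x Evaluation points.
#' @param q Entropic index, `1 <= q < 3`.
#' @param b Scale parameter (> 0), proportional to the mean of beta.
#' @param mu Shift parameter.
#' @param log Return the log-density?
#' @return Density values.
#' @export
qgaussian_pdf <- function(x, q, b, mu = 0, log = FALSE) {
  if (q < 1 || q >= 3) {
    abort("q must lie in [1, 3)", class = "superstat_domain_error")
  }
  stopifnot(b > 0)
  if (q < 1 + 1e-12) {
    return(dnorm(x, mean = mu, sd = 1 / sqrt(2 * b), log = log))
  }
  p <- 1 / (q - 1)                      # tail exponent, > 1/2 for q < 3
  a <- (q - 1) * b
  lC <- 0.5 * log(a / pi) + lgamma(p) - lgamma(p - 0.5)
  ld <- lC - p * log1p(a * (x - mu)^2)
  if (log) ld else exp(ld)
}

#' q-Gaussian sampler
#'
#' Samples via the Student-t representation: a q-Gaussian with index `q` is
#' a rescaled t distribution with `nu = (3 - q) / (q - 1)` degrees of
#' freedom, `x = mu + t_nu / sqrt((3 - q) b)`.
#'
#' @param size Number of draws.
#' @inheritParams qgaussian_pdf
#' @param seed Optional integer seed (RNG state preserved).
#' @return Numeric vector of draws.
#' @export
rqgaussian <- function(size, q, b, mu = 0, seed = NULL) {
  if (q < 1 || q >= 3) {
    abort("q must lie in [1, 3)", class = "superstat_domain_error")
  }
  stopifnot(b > 0)
  draw <- function() {
    if (q < 1 + 1e-12) return(rnorm(size, mu, 1 / sqrt(2 * b)))
    nu <- (3 - q) / (q - 1)
    mu + rt(size, df = nu) / sqrt((3 - q) * b)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' q-Gaussian induced by a chi-squared beta-law
#'
#' Integrating local Gaussians `N(0, 1/beta)` over a chi-squared beta-law
#' with degrees of freedom `n` and mean `beta0` yields exactly a q-Gaussian;
#' this returns the induced `(q, b)`: `q = (n + 3) / (n + 1)` and
#' `b = beta0 (n + 1) / (2 n)`.
#'
#' @param n Degrees of freedom of the chi-squared beta-law.
#' @param beta0 Mean of beta.
#' @return A list with elements `q` and `b`.
#' @export
chi2_superstat_qgaussian <- function(n, beta0) {
  stopifnot(n > 0, beta0 > 0)
  list(q = (n + 3) / (n + 1), b = beta0 * (n + 1) / (2 * n))
}

#' Superstatistical marginal by numerical integration
#'
#' Numerically integrates the local Gaussian `N(x; 0, 1/beta)` against a
#' beta-law density over `beta in (0, Inf)`, giving the aggregated
#' (marginal) fluctuation density. Used as the quadrature reference for the
#' q-Gaussian correspondence.
#'
#' @param x Evaluation points.
#' @inheritParams beta_pdf
#' @param rel.tol Quadrature relative tolerance.
#' @return Marginal density at each `x`.
#' @export
superstat_marginal_pdf <- function(x, family, params, rel.tol = 1e-10) {
  vapply(x, function(xi) {
    integrate(function(beta) {
      sqrt(beta / (2 * pi)) * exp(-beta * xi^2 / 2) *
        beta_pdf(beta, family, params)
    }, lower = 0, upper = Inf, rel.tol = rel.tol)$value
  }, numeric(1))
}

#' Gaussian kernel density estimate on a grid
#'
#' Plain Gaussian-kernel density estimate evaluated at the supplied grid,
#' with the bandwidth set by Scott's rule (`sd * n^(-1/5)`) or Silverman's
#' rule. Used for empirical PDF curves.
#'
#' @param values Numeric sample (>= 10 values, nonzero variance).
#' @param grid Evaluation grid.
#' @param bandwidth_rule `"scott"` (default) or `"silverman"`.
#' @return Density values on `grid`.
#' @export
kde_pdf <- function(values, grid, bandwidth_rule = c("scott", "silverman")) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  x <- values[!is.na(values)]
  if (length(x) < 10) {
    abort("need at least 10 values", class = "superstat_param_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s <= 0) {
    abort("zero-variance input; KDE degenerate",
          class = "superstat_degenerate_error")
  }
  n <- length(x)
  h <- switch(bandwidth_rule,
              scott = s * n^(-1 / 5),
              silverman = 0.9 * min(s, stats::IQR(x) / 1.34) * n^(-1 / 5))
  vapply(grid, function(g) mean(dnorm(g, mean = x, sd = h)), numeric(1))
}
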