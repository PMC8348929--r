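test_that("beta-law densities are normalized with the stated moments", {
  # chi-squared form: integrates to 1, mean beta0
  expect_equal(integrate(function(b) dbeta_chi2(b, 4, 2), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_equal(integrate(function(b) b * dbeta_chi2(b, 4, 2), 0, Inf,
                         rel.tol = 1e-10)$value, 2, tolerance = 1e-6)

  # concentration for large n: 99% of mass within beta0 +- 5%
  mass <- integrate(function(b) dbeta_chi2(b, 1e4, 2), 2 * 0.95, 2 * 1.05,
                    rel.tol = 1e-10)$value
  expect_gt(mass, 0.99)

  expect_equal(integrate(function(b) dbeta_invchi2(b, 6, 2), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(function(b) beta_pdf(b, "lognormal",
                                              list(mu_ln = 0.3,
                                                   sigma_ln = 0.8)),
                         0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_error(beta_pdf(-1, "chi2", list(n = 4, beta0 = 2)),
               class = "superstat_domain_error")
  expect_error(beta_pdf(1, "cauchy", list()),
               class = "superstat_config_error")
})

test_that("the chi-squared mixture reduces, normalizes, and shows two peaks", {
  b <- seq(0.01, 12, by = 0.01)
  # W = 1 collapses to the first component
  expect_equal(chi2_mixture_pdf(b, 1, 3, 20, 2), dbeta_chi2(b, 3, 2),
               tolerance = 1e-12)
  # equal degrees of freedom collapse regardless of W
  expect_equal(chi2_mixture_pdf(b, 0.5, 6, 6, 2), dbeta_chi2(b, 6, 2),
               tolerance = 1e-12)
  expect_equal(integrate(function(x) chi2_mixture_pdf(x, 0.3, 1, 30, 2),
                         0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)

  # boundary-adjacent peak plus an interior peak (dense grid oracle)
  dens <- chi2_mixture_pdf(b, 0.3, 1, 30, 2)
  d <- diff(dens)
  expect_lt(d[1], 0)                          # decreasing away from 0
  interior_max <- which(head(d, -1) > 0 & tail(d, -1) <= 0) + 1
  expect_gte(length(interior_max), 1)
  expect_gt(b[interior_max[1]], 1)            # near beta0 = 2
  expect_lt(b[interior_max[1]], 3)
})

test_that("q-Gaussian density is symmetric, normalized, Gaussian in the limit", {
  d <- seq(0.1, 5, by = 0.3)
  expect_equal(qgaussian_pdf(1 + d, 1.5, 1, mu = 1),
               qgaussian_pdf(1 - d, 1.5, 1, mu = 1))
  for (q in c(1, 1.3, 1.5, 2.5)) {
    expect_equal(integrate(function(x) qgaussian_pdf(x, q, 1), -Inf, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
  # q -> 1 reproduces the Gaussian with variance 1/(2b)
  expect_equal(qgaussian_pdf(0, 1.000001, 0.5),
               dnorm(0, sd = 1), tolerance = 1e-4)
  x <- seq(-3, 3, by = 0.5)
  expect_equal(qgaussian_pdf(x, 1, 0.5), dnorm(x, sd = 1),
               tolerance = 1e-12)
  expect_error(qgaussian_pdf(0, 3, 1), class = "superstat_domain_error")
  expect_error(qgaussian_pdf(0, 0.9, 1), class = "superstat_domain_error")
})

test_that("q-Gaussian sampler matches the quadrature CDF", {
  q <- 1.4; b <- 2
  xs <- rqgaussian(2e4, q, b, seed = 21)
  grid <- seq(-25, 25, length.out = 10001)
  pdf <- qgaussian_pdf(grid, q, b)
  h <- diff(grid)[1]
  cdf <- cumsum((head(pdf, -1) + tail(pdf, -1)) / 2 * h)
  cdf <- c(0, cdf) / max(cumsum((head(pdf, -1) + tail(pdf, -1)) / 2 * h))
  # empirical CDF against the numeric CDF: Kolmogorov-Smirnov distance
  emp <- ecdf(xs)
  ks <- max(abs(emp(grid) - cdf))
  expect_lt(ks, 0.02)
})

test_that("a chi-squared beta-law induces exactly a q-Gaussian marginal", {
  x <- seq(-8, 8, length.out = 81)
  for (n in c(2, 4, 8)) {
    marg <- superstat_marginal_pdf(x, "chi2", list(n = n, beta0 = 1))
    pred <- chi2_superstat_qgaussian(n, 1)
    expect_equal(pred$q, (n + 3) / (n + 1))
    qg <- qgaussian_pdf(x, pred$q, pred$b)
    expect_lt(max(abs(qg - marg) / marg), 1e-6)
  }
})

test_that("kde_pdf estimates simple densities and rejects degenerate input", {
  x <- withr::with_seed(22, rnorm(1e4))
  grid <- seq(-6, 6, length.out = 601)
  dens <- kde_pdf(x, grid)
  expect_equal(dens[grid == 0], 1 / sqrt(2 * pi), tolerance = 0.1)
  integral <- sum((head(dens, -1) + tail(dens, -1)) / 2 * diff(grid))
  expect_gt(integral, 0.99)
  expect_lt(integral, 1.01)
  expect_error(kde_pdf(rep(2, 50), grid),
               class = "superstat_degenerate_error")
  expect_error(kde_pdf(rnorm(5), grid), class = "superstat_param_error")
})
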