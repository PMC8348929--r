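test_that("log-normal MLE is closed form and recovers parameters", {
  b <- sample_beta(1e4, "lognormal", list(mu_ln = 0, sigma_ln = 0.5),
                   seed = 31)
  f <- fit_beta_family(b, "lognormal")
  expect_gt(f$params$sigma_ln, 0.48)
  expect_lt(f$params$sigma_ln, 0.52)
  expect_equal(f$params$mu_ln, mean(log(b)))
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)

  # degenerate: a single repeated value has zero log-variance
  expect_error(fit_beta_family(rep(2, 50), "lognormal"),
               class = "superstat_degenerate_error")
  expect_error(fit_beta_family(c(-1, 1, 2, 3, 4), "chi2"),
               class = "superstat_domain_error")
})

test_that("chi-squared MLE agrees with an independent gamma fitter", {
  b <- sample_beta(1e4, "chi2", list(n = 4, beta0 = 2), seed = 32)
  f <- fit_beta_family(b, "chi2")
  expect_gt(f$params$beta0, 1.9)
  expect_lt(f$params$beta0, 2.1)
  expect_true(f$converged)

  ref <- fitdistrplus::fitdist(b, "gamma", method = "mle")
  expect_equal(f$params$n / 2, unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(f$params$n / (2 * f$params$beta0),
               unname(ref$estimate["rate"]), tolerance = 1e-3)
  expect_equal(f$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("inverse chi-squared MLE recovers its parameters", {
  b <- sample_beta(1e4, "inv_chi2", list(n = 6, beta0 = 2), seed = 33)
  f <- fit_beta_family(b, "inv_chi2")
  expect_equal(f$params$n, 6, tolerance = 0.1)
  expect_equal(f$params$beta0, 2, tolerance = 0.05)
})

test_that("q-Gaussian MLE recovers shape and reduces to Gaussian", {
  x <- rqgaussian(2e4, q = 1.3, b = 1, mu = 0, seed = 34)
  f <- fit_qgaussian(x)
  expect_equal(f$params$q, 1.3, tolerance = 0.06)
  expect_equal(f$params$b, 1, tolerance = 0.1)
  expect_equal(f$params$mu, 0, tolerance = 0.05)

  g <- withr::with_seed(35, rnorm(2e4))
  fg <- fit_qgaussian(g)
  expect_lt(fg$params$q, 1.06)
  expect_equal(fg$params$b, 0.5, tolerance = 0.05)   # variance 1 = 1/(2b)

  expect_error(fit_qgaussian(rnorm(50)), class = "superstat_param_error")
})

test_that("mixture EM recovers the bimodal generating parameters", {
  b <- sample_beta(5000, "chi2_mixture",
                   list(W = 0.3, n1 = 1, n2 = 20, beta0 = 2), seed = 36)
  f <- fit_chi2_mixture(b)
  expect_equal(f$params$W, 0.3, tolerance = 0.1)
  expect_equal(f$params$beta0, 2, tolerance = 0.15 * 2)
  expect_lte(f$params$n1, f$params$n2)    # canonical labelling
  expect_true(f$converged)
})

test_that("the mixture likelihood nests the single chi-squared", {
  for (s in 37:39) {
    b <- sample_beta(500, "chi2", list(n = 6, beta0 = 2), seed = s)
    single <- fit_beta_family(b, "chi2")
    mix <- fit_chi2_mixture(b)
    expect_gte(mix$loglik, single$loglik - 1e-6)
    # ... but AIC penalizes the two extra parameters on single-law data
    expect_lt(single$aic, mix$aic)
  }
})

test_that("AIC ranking identifies the generating family", {
  # log-normal fixture: log-normal ranked first in >= 16 of 20 seeded runs
  wins <- 0
  for (s in 101:120) {
    b <- sample_beta(400, "lognormal", list(mu_ln = 0, sigma_ln = 1),
                     seed = s)
    cmp <- compare_fits(b)
    if (cmp$family[1] == "lognormal") wins <- wins + 1
  }
  expect_gte(wins, 16)

  # single chi-squared fixture: the mixture must not win
  not_mixture <- 0
  for (s in 121:130) {
    b <- sample_beta(400, "chi2", list(n = 6, beta0 = 2), seed = s)
    cmp <- compare_fits(b)
    if (cmp$family[1] != "chi2_mixture") not_mixture <- not_mixture + 1
  }
  expect_gte(not_mixture, 8)

  # one requested family: a table of one row
  b <- sample_beta(100, "chi2", list(n = 4, beta0 = 1), seed = 131)
  cmp1 <- compare_fits(b, families = "chi2")
  expect_equal(nrow(cmp1), 1)
  expect_equal(cmp1$rank, 1L)
})

test_that("estimator error shrinks with sample size", {
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    es <- vapply(1:3, function(r) {
      b <- sample_beta(n, "lognormal", list(mu_ln = 0, sigma_ln = 0.5),
                       seed = 1000 * r + log10(n))
      abs(fit_beta_family(b, "lognormal")$params$sigma_ln - 0.5)
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.005)
  expect_lt(err[3], err[2] + 0.002)
})

test_that("tidy and glance methods expose fit results", {
  b <- sample_beta(200, "chi2", list(n = 4, beta0 = 2), seed = 41)
  f <- fit_beta_family(b, "chi2")
  td <- tidy(f)
  expect_equal(td$term, c("n", "beta0"))
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)

  cmp <- compare_fits(b, families = c("chi2", "lognormal"))
  expect_equal(nrow(glance(cmp)), 1)
  expect_true(all(c("family", "term", "estimate") %in% names(tidy(cmp))))
})
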