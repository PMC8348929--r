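test_that("average kurtosis matches the brute-force moment computation", {
  x <- withr::with_seed(1, rnorm(5000) * rep(c(1, 3), each = 2500))
  for (w in c(64, 250, 1000)) {
    for (st in c(1, 7, w %/% 10)) {
      starts <- seq.int(1, length(x) - w + 1, by = st)
      direct <- vapply(starts, function(s) {
        u <- x[s:(s + w - 1)]
        m <- mean(u)
        mean((u - m)^4) / mean((u - m)^2)^2
      }, numeric(1))
      got <- average_kurtosis(x, w, st)
      expect_equal(as.numeric(got), mean(direct), tolerance = 1e-10)
    }
  }
})

test_that("average kurtosis of Gaussian noise is near 3 and errors on zero variance", {
  x <- withr::with_seed(2, rnorm(1e5))
  k <- average_kurtosis(x, 2000, 500)
  expect_gt(as.numeric(k), 2.9)
  expect_lt(as.numeric(k), 3.1)

  expect_error(average_kurtosis(rep(1, 100), 16, 4),
               class = "superstat_undefined_error")

  # variance mixing in a single window inflates kurtosis above Gaussian
  y <- withr::with_seed(3, c(rnorm(5000, sd = 1), rnorm(5000, sd = 5)))
  k2 <- average_kurtosis(y, length(y), 1)
  m <- mean(y)
  oracle <- mean((y - m)^4) / mean((y - m)^2)^2
  expect_equal(as.numeric(k2), oracle, tolerance = 1e-12)
  expect_gt(as.numeric(k2), 3)
})

test_that("windows containing gap markers are skipped, not propagated", {
  x <- withr::with_seed(4, rnorm(2000))
  x[500:520] <- NA
  k <- average_kurtosis(x, 100, 100)
  expect_true(is.finite(as.numeric(k)))
  expect_gt(attr(k, "n_skipped"), 0)
})

test_that("kurtosis_curve wraps average_kurtosis over the grid", {
  x <- withr::with_seed(5, rnorm(3e4))
  cv1 <- kurtosis_curve(x, window_grid_hours = 8, step_minutes = 15)
  expect_equal(nrow(cv1), 1)
  expect_equal(cv1$kappa_bar,
               as.numeric(average_kurtosis(x, 32, 3)))

  cv <- kurtosis_curve(x, window_grid_hours = c(250, 500, 1000),
                       step_minutes = 15)
  expect_true(all(cv$kappa_bar > 2.8 & cv$kappa_bar < 3.2))

  # variance switching on a long timescale raises kurtosis at large windows
  betas <- rep(c(1, 0.04), times = 20)
  y <- withr::with_seed(6,
    rnorm(40 * 500) * rep(1 / sqrt(betas), each = 500))
  cvy <- kurtosis_curve(y, window_grid_hours = c(10, 1000),
                        step_minutes = 15)
  expect_gt(cvy$kappa_bar[2], cvy$kappa_bar[1])
})

test_that("long_timescale interpolates the first upward crossing", {
  cv <- tibble::tibble(window_hours = c(10, 20), kappa_bar = c(2.5, 3.5))
  expect_equal(as.numeric(long_timescale(cv)), 15)

  # entirely platykurtic: no timescale is determined
  cv2 <- tibble::tibble(window_hours = c(5, 10, 20),
                        kappa_bar = c(2.1, 2.5, 2.9))
  expect_true(is.na(long_timescale(cv2)))

  # multiple crossings: the first upward one wins
  cv3 <- tibble::tibble(window_hours = c(5, 10, 20, 40),
                        kappa_bar = c(2, 4, 2, 6))
  expect_equal(as.numeric(long_timescale(cv3)), 7.5)

  expect_error(long_timescale(cv[1, ]), class = "superstat_param_error")
})

test_that("short_timescale recovers AR(1) relaxation times", {
  # phi = 0.9 at 15-min step: tau = -0.25 / log(0.9) ~ 2.37 h
  x <- withr::with_seed(7, as.numeric(
    stats::filter(rnorm(2e4, sd = sqrt(1 - 0.81)), 0.9, "recursive")))
  est <- short_timescale(x, step_minutes = 15)
  expect_equal(est$tau_hours, -0.25 / log(0.9), tolerance = 0.15)
  expect_false(est$resolution_limited)
  # exponential-fit cross-check agrees to within the same slack
  expect_equal(est$tau_fit_hours, -0.25 / log(0.9), tolerance = 0.2)

  # white noise: decay unresolved at the sampling step
  wn <- withr::with_seed(8, rnorm(5000))
  est2 <- short_timescale(wn, step_minutes = 15)
  expect_true(est2$resolution_limited)
  expect_equal(est2$tau_hours, 0.25)

  # OU fixture with tau_true = 1 h
  ou <- ou_series(4e4, tau_hours = 1, seed = 9)
  est3 <- short_timescale(ou, step_minutes = 15)
  expect_gt(est3$tau_hours, 0.7)
  expect_lt(est3$tau_hours, 1.3)
})

test_that("extract_betas computes per-window inverse variances", {
  # 50 windows of N(0, 4): beta concentrates near 1/4
  x <- withr::with_seed(10, rnorm(50 * 1000, sd = 2))
  bs <- extract_betas(x, T_hours = 250, step_minutes = 15)  # 1000 samples
  expect_equal(nrow(bs), 50)
  expect_gt(mean(bs$beta), 0.23)
  expect_lt(mean(bs$beta), 0.27)

  # floor rule: 10 windows plus half a window -> exactly 10 values
  y <- withr::with_seed(11, rnorm(10 * 96 + 48))
  bs2 <- extract_betas(y, T_hours = 24, step_minutes = 15)
  expect_equal(nrow(bs2), 10)

  # alternating variance epochs give a bimodal beta sample
  z <- withr::with_seed(12, rnorm(20 * 960) *
                          rep(rep(c(1, 0.1), 10), each = 960))
  bs3 <- extract_betas(z, T_hours = 240, step_minutes = 15)
  lo <- bs3$beta[bs3$beta < 10]
  hi <- bs3$beta[bs3$beta >= 10]
  expect_equal(length(lo), 10)
  expect_equal(length(hi), 10)
  expect_equal(median(lo), 1, tolerance = 0.2)
  expect_equal(median(hi), 100, tolerance = 0.2)

  expect_error(extract_betas(rnorm(100), T_hours = 10, step_minutes = 15),
               class = "superstat_insufficient_error")
  expect_error(extract_betas(rnorm(1000), T_hours = NA, step_minutes = 15),
               class = "superstat_param_error")
})

test_that("separation check reports the tau/T ratio", {
  s <- check_separation(16, 1)
  expect_equal(s$ratio, 0.0625)
  expect_true(s$pass)

  s2 <- check_separation(16, 8)
  expect_equal(s2$ratio, 0.5)
  expect_false(s2$pass)

  s3 <- check_separation(NA, 1)
  expect_false(s3$applicable)
  expect_true(is.na(s3$ratio))
})
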