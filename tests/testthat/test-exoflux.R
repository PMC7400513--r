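test_that("growth rate is recovered exactly from clean exponentials", {
  t <- seq(0, 48, by = 8)
  tc <- time_course(t, 0.8 * exp(0.0343 * t), kind = "cell_count")
  expect_equal(fit_growth_rate(tc)$mu, 0.0343, tolerance = 1e-12)
  flat <- time_course(t, rep(2, length(t)), kind = "cell_count")
  expect_equal(fit_growth_rate(flat)$mu, 0)
  expect_error(fit_growth_rate(time_course(0:2, c(1, 1, 0) + c(0, 0, 0),
                                           kind = "cell_count")),
               "positive")
})

test_that("growth-rate CIs cover the truth in most noisy replicates", {
  t <- seq(0, 32, by = 8)  # n = 5 points
  hits <- 0L
  set.seed(123)
  for (i in 1:100) {
    counts <- 0.8 * exp(0.0343 * t) * exp(rnorm(length(t), sd = 0.05))
    g <- fit_growth_rate(time_course(t, counts, kind = "cell_count"))
    if (g$ci[1] <= 0.0343 && 0.0343 <= g$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("degradation rate is recovered and clamped sensibly", {
  t <- seq(0, 48, by = 6)
  dec <- time_course(t, 8000 * exp(-0.00345 * t),
                     kind = "cell_free_concentration")
  expect_equal(fit_degradation_rate(dec)$k, 0.00345, tolerance = 1e-12)
  flat <- time_course(t, rep(5, length(t)), kind = "cell_free_concentration")
  expect_equal(fit_degradation_rate(flat)$k, 0)
  inc <- time_course(t, 10 * exp(0.01 * t), kind = "cell_free_concentration")
  expect_warning(res <- fit_degradation_rate(inc), "clamped")
  expect_equal(res$k, 0)
})

test_that("the amount model solves dA/dt = qX0 exp(mu t) - kA", {
  pars <- list(A0 = 4000, q = -82.7, X0 = 1.0, mu = 0.0343, k = 0.00345)
  expect_equal(do.call(amount_model, c(list(t = 0), pars[c(1, 2, 3, 4, 5)])),
               4000)
  t <- seq(0.5, 47.5, by = 0.5)
  h <- 1e-3
  A <- amount_model(t, pars$A0, pars$q, pars$X0, pars$mu, pars$k)
  dA <- (amount_model(t + h, pars$A0, pars$q, pars$X0, pars$mu, pars$k) -
           amount_model(t - h, pars$A0, pars$q, pars$X0, pars$mu, pars$k)) /
    (2 * h)
  rhs <- pars$q * pars$X0 * exp(pars$mu * t) - pars$k * A
  expect_lte(max(abs(dA - rhs) / pmax(abs(rhs), 1)), 1e-6)
  # limiting forms
  expect_equal(amount_model(10, 100, 2, 1, 0, 0), 120)
  expect_equal(amount_model(5, 100, 0, 1, 0.03, 0.00345),
               100 * exp(-0.00345 * 5) +
                 0 * (exp(0.03 * 5) - exp(-0.00345 * 5)))
})

test_that("noise-free exchange rates are recovered to six significant digits", {
  t <- seq(0, 24, by = 3)
  truth <- list(A0 = 4000, q = -82.7, X0 = 1.0, mu = 0.0343, k = 0.00345)
  y <- amount_model(t, truth$A0, truth$q, truth$X0, truth$mu, truth$k)
  res <- fit_exchange_rate(time_course(t, y), mu = truth$mu, X0 = truth$X0,
                           k = truth$k, n_boot = 0)
  expect_equal(res$q, -82.7, tolerance = 1e-7)
  expect_equal(res$A0, 4000, tolerance = 1e-7)
  expect_equal(res$direction, "uptake")
  # q = 0, k = 0: constant amounts
  y0 <- amount_model(t, 500, 0, 1, 0.03, 0)
  expect_equal(y0, rep(500, length(t)))
  # positive q, k = 0: fitted curve strictly increasing
  ys <- amount_model(t, 100, 12, 1, 0.03, 0)
  expect_true(all(diff(ys) > 0))
})

test_that("bootstrap CIs for q have near-nominal coverage", {
  t <- seq(0, 40, by = 8)
  truth <- list(A0 = 8000, q = -82.7, X0 = 0.8, mu = 0.0343, k = 0.00345)
  y_true <- amount_model(t, truth$A0, truth$q, truth$X0, truth$mu, truth$k)
  hits <- 0L
  n_rep <- 200L
  set.seed(99)
  seeds <- sample.int(1e6, n_rep)
  for (i in seq_len(n_rep)) {
    y <- y_true * (1 + rnorm(length(t), sd = 0.02))
    res <- fit_exchange_rate(time_course(t, pmax(y, 0)), mu = truth$mu,
                             X0 = truth$X0, k = truth$k, n_boot = 300,
                             seed = seeds[i])
    if (res$ci[1] <= 82.7 && 82.7 <= res$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("comparative reporting arithmetic matches its definitions", {
  expect_equal(percent_change(82.7, 52.7), -36)
  expect_equal(percent_change(13.9, 1.5), -89)
  expect_equal(percent_change(8.7, 9.6), 10)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero")
  expect_equal(flux_ratio(1087.7, 578.8), 1.88)
  expect_equal(flux_ratio(1009.8, 533.5), 1.89)
  expect_equal(flux_ratio(0, 7), 0)
  expect_error(flux_ratio(1, 0), "positive")
})
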