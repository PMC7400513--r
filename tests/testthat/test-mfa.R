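make_cal_problem <- function(ms, n_starts = 1L, seed = 1L, ...) {
  cal <- calibration_network()
  prob <- mfa_problem(cal$model, cal$fragments, cal$tracers, ms,
                      fit_options(n_starts = n_starts, seed = seed, ...))
  list(cal = cal, prob = prob)
}

noise_free_measurements <- function(cal) {
  emunet <- decompose_emu(cal$model, cal$fragments)
  backbone <- simulate_mids(emunet, cal$fluxes, cal$tracers$exp1)
  rows <- lapply(names(backbone), function(id) {
    data.frame(experiment = "exp1", fragment = id,
               mass = seq_along(backbone[[id]]) - 1L,
               mean = backbone[[id]], sd = 0.01, stringsAsFactors = FALSE)
  })
  soft <- data.frame(reaction = names(cal$soft_true),
                     value = unname(cal$soft_true), rel_sd = 0.05,
                     stringsAsFactors = FALSE)
  measurement_set(do.call(rbind, rows), soft)
}

test_that("the RSS decomposes exactly into its per-measurement terms", {
  cal <- calibration_network()
  ms <- noise_free_measurements(cal)
  x <- make_cal_problem(ms)
  # noise-free data at the generating fluxes: RSS = 0
  expect_equal(residual_ss(x$prob, fluxes = cal$fluxes), 0, tolerance = 1e-16)

  # one MID element off by exactly one SD contributes exactly 1.0
  ms2 <- ms
  ms2$mids$mean[3] <- ms2$mids$mean[3] + 0.01
  x2 <- make_cal_problem(ms2)
  expect_equal(residual_ss(x2$prob, fluxes = cal$fluxes), 1, tolerance = 1e-9)

  # a soft flux off by exactly 5% contributes exactly 1.0
  ms3 <- ms
  ms3$soft$value[1] <- ms3$soft$value[1] * 1.05
  x3 <- make_cal_problem(ms3)
  expect_equal(residual_ss(x3$prob, fluxes = cal$fluxes),
               (0.05 / (0.05 * 1.05))^2, tolerance = 1e-9)

  # removing a measurement lowers the RSS by exactly its term
  msn <- simulate_calibration_dataset(cal, seed = 5)
  xa <- make_cal_problem(msn)
  full <- residual_ss(xa$prob, fluxes = cal$fluxes)
  drop_row <- msn$mids[1, ]
  term <- ((mfa13c:::assemble_fragment_mids(
    xa$prob$emunet,
    mfa13c:::emu_solve(xa$prob$emunet,
                       mfa13c:::directed_flux_values(cal$model, cal$fluxes),
                       cal$tracers$exp1, natural_c13_fraction()),
    list())[[drop_row$fragment]][drop_row$mass + 1] -
      drop_row$mean) / drop_row$sd)^2
  msr <- msn
  msr$mids <- msr$mids[-1, ]
  xb <- make_cal_problem(msr)
  expect_equal(full - residual_ss(xb$prob, fluxes = cal$fluxes), term,
               tolerance = 1e-9)
})

test_that("fitting is deterministic for a fixed seed", {
  cal <- calibration_network()
  ms <- simulate_calibration_dataset(cal, seed = 21)
  f1 <- fit_calibration_dataset(cal, ms, n_starts = 3L, seed = 77)
  f2 <- fit_calibration_dataset(cal, ms, n_starts = 3L, seed = 77)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$fluxes$net, f2$fluxes$net)
  expect_identical(f1$theta, f2$theta)
})

test_that("noise-free fits recover the generating fluxes", {
  cal <- calibration_network()
  ms <- noise_free_measurements(cal)
  fit <- fit_calibration_dataset(cal, ms, n_starts = 3L, seed = 2)
  expect_lt(fit$rss, 1e-6)
  rel <- abs(fit$fluxes$net - cal$fluxes$net) /
    pmax(abs(cal$fluxes$net), 1e-9)
  expect_lt(max(rel), 1e-3)
})

test_that("noise-free paper-scenario data recover the reference-network fluxes", {
  scen <- make_scenario(seed = 11)
  mm <- simulate_mid_measurements(scen, noise_sd = 0)
  prob <- mfa_problem(scen$model, read_fragment_table(), scen$tracers,
                      mm$parental$measurements,
                      fit_options(n_starts = 1, seed = 11, maxit = 500))
  truth <- scen$conditions$parental$fluxes
  th_true <- mfa13c:::encode_theta(prob, truth, scen$mix)
  set.seed(2)
  th0 <- th_true * runif(length(th_true), 0.85, 1.15)
  fit <- fit_fluxes(prob, init = th0)
  expect_lt(fit$rss, 1e-6)
  rel <- abs(fit$fluxes$net - truth$net) / pmax(abs(truth$net), 1e-6)
  expect_lt(max(rel), 1e-3)  # within 0.1% of the generating fluxes
  # mixing fractions are recovered too
  expect_equal(fit$mix$mal_mix, scen$mix$mal_mix, tolerance = 1e-2)
})

test_that("the chi-squared verdict follows the stated threshold rule", {
  expect_true(goodness_of_fit(list(rss = 0, dof = 7))$pass)
  g <- goodness_of_fit(list(rss = 18.4, dof = 10))
  expect_equal(g$threshold, qchisq(0.95, 10))
  expect_false(g$pass)  # 18.4 > 18.307
  expect_true(goodness_of_fit(list(rss = 18.2, dof = 10))$pass)
  expect_error(goodness_of_fit(list(rss = 1, dof = 0)), "overparameterized")
})

test_that("90% grid-search intervals nest inside 95% intervals", {
  cal <- calibration_network()
  ms <- simulate_calibration_dataset(cal, seed = 31)
  fit <- fit_calibration_dataset(cal, ms, seed = 31)
  for (r in c("R_up2", "R_ac")) {
    ci95 <- grid_search_ci(fit, r, level = 0.95)
    ci90 <- grid_search_ci(fit, r, level = 0.90)
    expect_gte(ci90$lower, ci95$lower - 1e-6)
    expect_lte(ci90$upper, ci95$upper + 1e-6)
    expect_lte(ci95$lower, ci95$best)
    expect_gte(ci95$upper, ci95$best)
  }
})

test_that("hard-constrained reactions collapse to point intervals", {
  cal <- calibration_network()
  ms <- simulate_calibration_dataset(cal, seed = 8)
  ms$fixed <- c(R_up2 = 50)
  fit <- fit_calibration_dataset(cal, ms, seed = 8)
  ci <- grid_search_ci(fit, "R_up2")
  expect_true(ci$collapsed)
  expect_equal(ci$lower, 50)
  expect_equal(ci$upper, 50)
})

test_that("structurally unidentifiable exchange fluxes are reported ND", {
  # a <-> b where b is only drained: back-exchange is invisible
  m <- reversible_model()
  frag <- list(fB = fragment_spec("fB", "b", 1:3))
  tr <- list(exp1 = list(in_e = tracer_spec("in_e", 1:2, 0.99)))
  emunet <- decompose_emu(m, frag)
  fl <- flux_vector(m, c(UP = 10, AB = 10, OUT = 10), xch = c(AB = 5))
  backbone <- simulate_mids(emunet, fl, tr$exp1)
  rows <- data.frame(experiment = "exp1", fragment = "fB",
                     mass = 0:3, mean = backbone$fB, sd = 0.01,
                     stringsAsFactors = FALSE)
  soft <- data.frame(reaction = "UP", value = 10, rel_sd = 0.05,
                     stringsAsFactors = FALSE)
  prob <- mfa_problem(m, frag, tr, measurement_set(rows, soft),
                      fit_options(n_starts = 1))
  fit <- fit_fluxes(prob, init = list(fluxes = fl))
  ci <- grid_search_ci(fit, "AB", what = "xch", max_steps = 12L)
  expect_true(is.na(ci$upper))
})

test_that("CI overlap decides significance with touching counted as overlap", {
  mk <- function(lo, hi) list(lower = lo, upper = hi, best = (lo + hi) / 2)
  expect_true(compare_cis(mk(1, 2), mk(3, 4))$significant)
  expect_false(compare_cis(mk(1, 3), mk(2, 4))$significant)
  expect_false(compare_cis(mk(1, 2), mk(2, 3))$significant)
  expect_equal(compare_cis(mk(1, 2), mk(3, 4))$direction, "increased")
  expect_equal(compare_cis(mk(3, 4), mk(1, 2))$direction, "decreased")
  expect_true(is.na(compare_cis(mk(1, NA), mk(2, 3))$significant))
})

test_that("stationarity assessment separates drift from noise", {
  times <- c(24, 29, 32)
  grid <- expand.grid(time = times, replicate = 1:3)
  flat <- data.frame(fragment = "f", time = grid$time,
                     replicate = grid$replicate, mass = 0,
                     value = 0.5)
  expect_true(assess_stationarity(flat)$stationary)

  set.seed(4)
  drift <- data.frame(fragment = "f", time = grid$time,
                      replicate = grid$replicate, mass = 0,
                      value = 0.5 + 0.05 * (grid$time - 24) +
                        rnorm(nrow(grid), sd = 0.01))
  expect_false(assess_stationarity(drift)$stationary)

  tiny <- data.frame(fragment = "f", time = grid$time,
                     replicate = grid$replicate, mass = 0,
                     value = 0.5 + 1e-5 * (grid$time - 24) +
                       rnorm(nrow(grid), sd = 0.01))
  expect_true(assess_stationarity(tiny)$stationary)

  single <- data.frame(fragment = "f", time = 24, replicate = 1, mass = 0,
                       value = 0.5)
  expect_true(is.na(assess_stationarity(single)$stationary))
})
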