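test_that("scenario ground truth honours the printed anchors and steady state", {
  scen <- make_scenario(seed = 1)
  S <- stoichiometric_matrix(scen$model)
  for (cn in names(scen$conditions)) {
    fl <- scen$conditions[[cn]]$fluxes
    expect_lte(max(abs(S %*% fl$net)), 1e-9 * max(abs(fl$net)))
  }
  par <- scen$conditions$parental$fluxes
  dim_ <- scen$conditions$fhdim$fluxes
  expect_equal(flux_ratio(par$net[["LDH"]], par$net[["HK"]]), 1.88)
  expect_equal(flux_ratio(dim_$net[["LDH"]], dim_$net[["HK"]]), 1.89)
  # FH reverse/forward ratio is strongly reduced in the FH-diminished state
  ratio <- function(fl) fl$xch[["FH"]] / (fl$net[["FH"]] + fl$xch[["FH"]])
  expect_lt(ratio(dim_), ratio(par))
  expect_gt(ratio(par), 0.99)
  # TCA-side fluxes all decrease; pyruvate carboxylase stays put
  for (r in c("MPC1", "PDH", "CS", "AKGDH", "SDH", "FH", "MDH")) {
    expect_lt(dim_$net[[r]], par$net[[r]])
  }
  expect_equal(dim_$net[["PC"]], par$net[["PC"]])
})

test_that("synthetic datasets are byte-identical for identical seeds", {
  s1 <- make_scenario(seed = 5)
  s2 <- make_scenario(seed = 5)
  expect_identical(simulate_timecourses(s1), simulate_timecourses(s2))
  frag <- read_fragment_table()[c("fum", "mal")]
  m1 <- simulate_mid_measurements(s1, fragments = frag)
  m2 <- simulate_mid_measurements(s2, fragments = frag)
  expect_identical(m1$parental$measurements$mids,
                   m2$parental$measurements$mids)
  expect_identical(m1$fhdim$measurements$soft, m2$fhdim$measurements$soft)
})

test_that("noise-free time courses round-trip every exchange rate", {
  scen <- make_scenario(seed = 3)
  tc <- simulate_timecourses(scen)
  # rebuild noise-free series directly from the generator's model
  for (cn in c("parental", "fhdim")) {
    cond <- scen$conditions[[cn]]
    for (met in c("glucose", "glutamine", "lactate", "proline")) {
      q <- mfa13c:::scenario_q(scen, cn, met)
      k <- if (met == "glutamine") scen$degradation[["glutamine"]] else 0
      t <- seq(0, 40, by = 4)
      y <- amount_model(t, scen$A0[[met]], q, cond$X0, cond$mu, k)
      res <- fit_exchange_rate(time_course(t, y), mu = cond$mu, X0 = cond$X0,
                               k = k, n_boot = 0)
      expect_equal(res$q, q, tolerance = 1e-7)
    }
  }
  # the cell-free glutamine series decays at the configured constant
  cf <- tc[tc$kind == "cell_free_concentration", ]
  expect_gt(nrow(cf), 0)
  expect_true(all(tc$value >= 0))
})

test_that("noisy exchange-rate estimates track the scenario anchors", {
  scen <- make_scenario(seed = 17)
  tc <- simulate_timecourses(scen)
  exo <- fit_all_exchange_rates(tc, n_boot = 50, seed = 17)
  expect_equal(exo$parental$mu$mu, 0.0343, tolerance = 0.05)
  expect_equal(exo$fhdim$mu$mu, 0.0208, tolerance = 0.08)
  expect_equal(exo$k_glutamine, 0.00345, tolerance = 0.25)
  r <- exo$parental$rates
  expect_equal(r$flux[r$metabolite == "glucose"], 578.8, tolerance = 0.05)
  expect_equal(r$flux[r$metabolite == "lactate"], 1087.7, tolerance = 0.03)
  expect_equal(r$direction[r$metabolite == "glucose"], "uptake")
  expect_equal(r$direction[r$metabolite == "lactate"], "secretion")
})

test_that("noise-free MID measurements reproduce the backbone truth exactly", {
  scen <- make_scenario(seed = 2)
  frag <- read_fragment_table()[c("pyr", "fum", "glu")]
  mm <- simulate_mid_measurements(scen, fragments = frag, noise_sd = 0)
  for (cn in names(mm)) {
    mids <- mm[[cn]]$measurements$mids
    for (exp_id in unique(mids$experiment)) {
      for (fr in unique(mids$fragment)) {
        got <- mids$mean[mids$experiment == exp_id & mids$fragment == fr]
        want <- mm[[cn]]$truth_backbone[[exp_id]][[fr]]
        expect_lte(max(abs(got - want)), 1e-9)
      }
    }
    expect_equal(unname(mm[[cn]]$measurements$soft$value),
                 unname(c(scen$conditions[[cn]]$fluxes$net[["HK"]],
                          scen$conditions[[cn]]$fluxes$net[["LDH"]])))
  }
})

test_that("replicates are stationary by construction and noise has the set scale", {
  scen <- make_scenario(seed = 9)
  frag <- read_fragment_table()["fum"]
  mm <- simulate_mid_measurements(scen, fragments = frag, noise_sd = 0)
  reps <- mm$parental$replicates
  st <- assess_stationarity(data.frame(
    fragment = paste(reps$experiment, reps$fragment),
    time = reps$time, replicate = reps$replicate, mass = reps$mass,
    value = reps$value))
  expect_true(all(st$stationary))

  # empirical raw-space noise SD across many replicates stays near 0.01
  cal <- calibration_network()
  draws <- vapply(1:1000, function(i) {
    simulate_calibration_dataset(cal, seed = 5000 + i)$mids$mean[2]
  }, 0)
  expect_equal(sd(draws), 0.01, tolerance = 0.1)
})

test_that("the end-to-end pipeline produces coherent comparative reports", {
  res <- end_to_end(seed = 42, options = fit_options(n_starts = 1, seed = 42),
                    n_boot = 50)
  expect_true("percent_change" %in% names(res$exchange$table))
  expect_setequal(res$ledger_table$pathway,
                  c("Glycolysis", "TCA cycle", "Total net"))
  expect_true(all(c("difference", "fold_change") %in%
                    names(res$ledger_table)))
  # both fits statistically acceptable and close to the generating truth
  for (cn in c("parental", "fhdim")) {
    expect_true(goodness_of_fit(res$fits[[cn]])$pass)
  }
  rec <- res$recovery
  key <- rec$reaction %in% c("PDH", "FH", "GDH", "CS")
  expect_lt(max(rec$abs_error[key] / pmax(rec$truth[key], 1)), 0.25)
})

test_that("an unlabelled-tracer control carries only backbone natural abundance", {
  scen <- make_scenario(seed = 4)
  scen$tracers <- list(ctrl = list())  # no tracer: natural-abundance feed
  frag <- read_fragment_table()[c("pyr", "glu")]
  mm <- simulate_mid_measurements(scen, fragments = frag, noise_sd = 0)
  nat <- natural_c13_fraction()
  mids <- mm$parental$measurements$mids
  for (fr in unique(mids$fragment)) {
    m0 <- mids$mean[mids$fragment == fr & mids$mass == 0]
    n <- sum(mids$fragment == fr) - 1L
    expect_equal(m0, (1 - nat)^n, tolerance = 1e-6)
  }
})
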