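test_that("reference model loads with the expected TCA machinery and validates cleanly", {
  model <- reference_model()
  expect_true(all(c("MPC1", "MPC2", "PDH", "CS", "IDH", "AKGDH", "SDH",
                    "FH", "MDH") %in% names(model$reactions)))
  report <- validate_model(model)
  expect_equal(nrow(report$findings), 0L)
  # symmetric fumarate generates the reversed alternative atom map for FH
  fh_maps <- model$reactions[["FH"]]$maps
  expect_equal(length(fh_maps), 2L)
  expect_equal(fh_maps[[1]]$weight + fh_maps[[2]]$weight, 1)
  subs <- lapply(fh_maps, function(m) m$substrates[[1]])
  expect_true(any(vapply(subs, function(s) identical(s, rev(letters[1:4])),
                         TRUE)))
})

test_that("malformed models are rejected with informative errors", {
  mets <- list(list("x_e", "extracellular", 2, 0, 0),
               list("a", "cytosol", 2, 0, 1),
               list("b", "cytosol", 1, 0, 1))
  expect_error(
    toy_model(mets, list(list("R1", "x_e (ab) --> b (a)", 0, 0, 10))),
    "carbon imbalance.*R1")
  expect_error(
    toy_model(mets, list(list("R1", "x_e (ab) --> ghost (ab)", 0, 0, 10))),
    "not declared")
  expect_error(
    toy_model(mets, list(list("R1", "x_e (ab) --> b (abc)", 0, 0, 10))),
    "atom map")
})

test_that("validation reports dead ends and degenerate mixing pools", {
  m <- toy_model(
    mets = list(list("in_e", "extracellular", 2, 0, 0),
                list("a", "cytosol", 2, 0, 1),
                list("orphan", "cytosol", 2, 0, 1),
                list("pool", "mixing", 2, 0, 0)),
    rxns = list(list("UP", "in_e (ab) --> a (ab)", 0, 0, 10),
                list("MK", "a (ab) --> orphan (ab)", 0, 0, 10)),
    mixing = list(pool = "a"))
  rep <- validate_model(m)
  expect_true("dead_end" %in% rep$findings$type)
  expect_true(any(rep$findings$type == "mixing_rule" &
                    rep$findings$subject == "pool"))
})

test_that("parameterization dimension matches an independent rank oracle", {
  chain <- chain_model()
  p <- parameterize_model(chain, fixed = c(UP = 10))
  expect_equal(p$n_free, 0L)
  fl <- expand_fluxes(p)
  expect_equal(unname(fl$net), rep(10, 3))

  diamond <- diamond_model()
  p2 <- parameterize_model(diamond, fixed = c(UP = 10))
  # independent oracle: free dims = n_rxn - rank of stacked constraints
  A <- rbind(stoichiometric_matrix(diamond),
             UProw = as.numeric(names(diamond$reactions) == "UP"))
  oracle_rank <- sum(svd(A)$d > 1e-9)
  expect_equal(p2$n_free, length(diamond$reactions) - oracle_rank)
  expect_equal(p2$n_free, 1L)

  model <- reference_model()
  fixed <- c(HK = 578.8, GLNUP = 82.7, LDH = 1087.7, PYRX = 61.7,
             ALAT = 17.1, PROX = 13.9, SERUP = 22.0, BIOMASS = 0.0343)
  p3 <- parameterize_model(model, fixed = fixed)
  A3 <- stoichiometric_matrix(model)
  E <- matrix(0, length(fixed), ncol(A3), dimnames = list(names(fixed),
                                                          colnames(A3)))
  for (r in names(fixed)) E[r, r] <- 1
  oracle3 <- sum(svd(rbind(A3, E))$d > 1e-7)
  expect_equal(p3$n_free, length(model$reactions) - oracle3)
})

test_that("expanded flux vectors satisfy steady state and round-trip free values", {
  model <- reference_model()
  p <- parameterize_model(model, fixed = c(BIOMASS = 0.03))
  S <- stoichiometric_matrix(model)
  set.seed(42)
  for (i in 1:5) {
    free <- stats::setNames(runif(p$n_free, 5, 50), p$free_ids)
    fl <- expand_fluxes(p, free, check_bounds = FALSE)
    expect_lte(max(abs(S %*% fl$net)), 1e-9 * max(1, max(abs(fl$net))))
    # round trip: free coordinates are read back exactly
    expect_identical(unname(fl$net[p$free_ids]), unname(free))
  }
})

test_that("bound violations and inconsistent constraints are caught", {
  diamond <- diamond_model()
  p <- parameterize_model(diamond, fixed = c(UP = 10))
  # forcing one branch above the uptake makes the other negative
  free_hi <- stats::setNames(rep(11, p$n_free), p$free_ids)
  expect_error(expand_fluxes(p, free_hi), "bound violation")
  fl <- expand_fluxes(p, free_hi, check_bounds = FALSE)
  expect_gt(length(fl$violations), 0)
  expect_error(parameterize_model(chain_model(), fixed = c(UP = 10, SEC = 5)),
               "inconsistent")
})

test_that("symmetry alternatives leave stoichiometry unchanged", {
  m_sym <- toy_tca_model(TRUE)
  m_asym <- toy_tca_model(FALSE)
  expect_identical(stoichiometric_matrix(m_sym),
                   stoichiometric_matrix(m_asym))
})
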