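test_that("chain decomposition yields the minimal EMU set", {
  m <- chain_model()
  net <- decompose_emu(m, list(fragment_spec("fB", "b", 1:2)))
  expect_setequal(names(net$nodes), c("in_e[1,2]", "a[1,2]", "b[1,2]"))
  expect_equal(length(net$input_keys), 1L)
})

test_that("unlabeled tracer in a 13C-free world gives pure M+0", {
  m <- chain_model()
  net <- decompose_emu(m, list(fragment_spec("fB", "b", 1:2)))
  fl <- flux_vector(m, c(UP = 5, AB = 5, SEC = 5))
  mids <- simulate_mids(net, fl, tracers = list(), abundance = zero_c13_table())
  expect_equal(mids$fB, c(1, 0, 0))
})

test_that("purity acts positionally: fully labeled substrate gives binomial MIDs", {
  m <- chain_model()
  net <- decompose_emu(m, list(fragment_spec("fB", "b", 1:2)))
  fl <- flux_vector(m, c(UP = 5, AB = 5, SEC = 5))
  p <- 0.97
  mids <- simulate_mids(net, fl,
                        tracers = list(in_e = tracer_spec("in_e", 1:2, p)),
                        abundance = zero_c13_table())
  expect_equal(mids$fB, c((1 - p)^2, 2 * p * (1 - p), p^2), tolerance = 1e-12)
})

test_that("EMU cascade matches the brute-force isotopomer oracle on toy networks", {
  worst <- 0
  check <- function(model, fluxes, tracers, frags, mix = list()) {
    net <- decompose_emu(model, frags)
    emu <- simulate_mids(net, fluxes, tracers, mix)
    bf <- brute_force_mids(model, fluxes, tracers, frags, mix)
    for (id in names(emu)) worst <<- max(worst, max(abs(emu[[id]] - bf[[id]])))
  }
  # 1. linear chain
  m1 <- chain_model()
  check(m1, flux_vector(m1, c(UP = 5, AB = 5, SEC = 5)),
        list(in_e = tracer_spec("in_e", 1, 0.99)),
        list(fragment_spec("fB", "b", 1:2)))
  # 2. TCA loop with symmetric fumarate/succinate and reversible FH
  m2 <- toy_tca_model(TRUE)
  check(m2, toy_tca_fluxes(m2, v = 1.7, fh_xch = 2.3),
        list(accoa_e = tracer_spec("accoa_e", 1:2, 0.98)),
        list(fragment_spec("mal", "mal", 1:4),
             fragment_spec("akg", "akg", 1:5),
             fragment_spec("cit", "cit", 1:6)))
  # 3. condensation + asymmetric split
  m3 <- condense_model()
  check(m3, flux_vector(m3, c(UX = 3, UY = 3, CON = 3, SPL = 3)),
        list(x_e = tracer_spec("x_e", 1:2, 0.99),
             y_e = tracer_spec("y_e", 2, 0.95)),
        list(fragment_spec("fP", "p_e", 1:2),
             fragment_spec("fQ", "q_e", 1:3)))
  # 4. reversible interconversion with exchange
  m4 <- reversible_model()
  check(m4, flux_vector(m4, c(UP = 2, AB = 2, OUT = 2), xch = c(AB = 7)),
        list(in_e = tracer_spec("in_e", c(1, 3), 0.99)),
        list(fragment_spec("fA", "a", 1:3), fragment_spec("fB", "b", 1:3)))
  # 5. two-substrate dilution with a mixing pool
  m5 <- dilution_model()
  check(m5, flux_vector(m5, c(U1 = 4, T12 = 4, U2 = 6, O2 = 10),
                        xch = c(T12 = 3)),
        list(s1_e = tracer_spec("s1_e", 1:2, 0.99)),
        list(fragment_spec("fmix", "a_mix", 1:2)),
        mix = list(a_mix = c(a1 = 0.35, a2 = 0.65)))
  expect_lte(worst, 1e-8)
})

test_that("toy TCA EMU count matches exhaustive reachability enumeration", {
  m <- toy_tca_model(TRUE)
  frags <- list(fragment_spec("mal", "mal", 1:4))
  net <- decompose_emu(m, frags)
  # independent oracle: breadth-first closure over (metabolite, carbon set)
  # pairs using the raw directed events
  events <- mfa13c:::directed_events(m)
  seen <- character(0)
  queue <- list(list(met = "mal", pos = 1:4))
  keyf <- function(met, pos) paste0(met, "[", paste(pos, collapse = ","), "]")
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    k <- keyf(nd$met, nd$pos)
    if (k %in% seen) next
    seen <- c(seen, k)
    for (e in events) {
      for (tg in e$targets) {
        if (tg$met != nd$met) next
        want <- tg$letters[nd$pos]
        for (src in e$sources) {
          hit <- which(src$letters %in% want)
          if (length(hit))

            queue[[length(queue) + 1]] <- list(met = src$met, pos = sort(hit))
        }
      }
    }
  }
  expect_equal(sort(names(net$nodes)), sort(seen))
})

test_that("symmetric molecules scramble positional labelling; asymmetric do not", {
  mk <- function(sym) toy_model(
    mets = list(list("in_e", "extracellular", 2, 0, 0),
                list("x", "cytosol", 2, as.integer(sym), 1),
                list("out_e", "extracellular", 2, 0, 0)),
    rxns = list(list("UP", "in_e (ab) --> x (ab)", 0, 0, 10),
                list("OUT", "x (ab) --> out_e (ab)", 0, 0, 10)))
  tr <- list(in_e = tracer_spec("in_e", 1, 1))  # label carbon 1 only
  frags <- list(fragment_spec("f1", "x", 1), fragment_spec("f2", "x", 2))
  fl <- function(m) flux_vector(m, c(UP = 2, OUT = 2))
  m_sym <- mk(TRUE)
  mids_sym <- simulate_mids(decompose_emu(m_sym, frags), fl(m_sym), tr,
                            abundance = zero_c13_table())
  expect_equal(mids_sym$f1, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(mids_sym$f1, mids_sym$f2, tolerance = 1e-12)
  m_asym <- mk(FALSE)
  mids_asym <- simulate_mids(decompose_emu(m_asym, frags), fl(m_asym), tr,
                             abundance = zero_c13_table())
  expect_equal(mids_asym$f1, c(0, 1), tolerance = 1e-12)
  expect_equal(mids_asym$f2, c(1, 0), tolerance = 1e-12)

  # within the symmetric TCA loop both fumarate halves carry identical MIDs
  m2 <- toy_tca_model(TRUE)
  halves <- list(fragment_spec("f12", "fum", 1:2),
                 fragment_spec("f34", "fum", 3:4))
  mids2 <- simulate_mids(decompose_emu(m2, halves), toy_tca_fluxes(m2),
                         list(accoa_e = tracer_spec("accoa_e", 1, 1)),
                         abundance = zero_c13_table())
  expect_equal(mids2$f12, mids2$f34, tolerance = 1e-12)
})

test_that("reversible equilibration copies the upstream MID downstream", {
  m <- reversible_model()
  net <- decompose_emu(m, list(fragment_spec("fA", "a", 1:3),
                               fragment_spec("fB", "b", 1:3)))
  fl <- flux_vector(m, c(UP = 2, AB = 2, OUT = 2), xch = c(AB = 50))
  mids <- simulate_mids(net, fl, list(in_e = tracer_spec("in_e", 1, 0.99)))
  expect_equal(mids$fA, mids$fB, tolerance = 1e-9)
})

test_that("unreachable and singular configurations raise named errors", {
  m <- toy_model(
    mets = list(list("in_e", "extracellular", 2, 0, 0),
                list("a", "cytosol", 2, 0, 1),
                list("island", "cytosol", 2, 0, 1),
                list("out_e", "extracellular", 2, 0, 0)),
    rxns = list(list("UP", "in_e (ab) --> a (ab)", 0, 0, 10),
                list("OUT", "a (ab) --> out_e (ab)", 0, 0, 10),
                list("ISL", "island (ab) --> out_e (ab)", 0, 0, 10)))
  expect_error(decompose_emu(m, list(fragment_spec("fi", "island", 1:2))),
               "unreachable EMU")
  m2 <- chain_model()
  net2 <- decompose_emu(m2, list(fragment_spec("fB", "b", 1:2)))
  fl0 <- flux_vector(m2, c(UP = 0, AB = 0, SEC = 0))
  expect_error(simulate_mids(net2, fl0, list()), "singular EMU layer")
})

test_that("MIDs are normalized and invariant to flux rescaling", {
  m <- toy_tca_model(TRUE)
  net <- decompose_emu(m, list(fragment_spec("cit", "cit", 1:6)))
  tr <- list(accoa_e = tracer_spec("accoa_e", 1:2, 0.98))
  a <- simulate_mids(net, toy_tca_fluxes(m, v = 1, fh_xch = 0.4), tr)
  b <- simulate_mids(net, toy_tca_fluxes(m, v = 57.3, fh_xch = 0.4 * 57.3), tr)
  expect_lte(abs(sum(a$cit) - 1), 1e-9)
  expect_lte(max(abs(a$cit - b$cit)), 1e-9)
})

test_that("tracer mixtures are linear at the substrate EMU itself", {
  nat13 <- natural_c13_fraction()
  sp1 <- tracer_spec("s", 1:2, purity = 0.99, fraction = 0.6)
  sp2 <- tracer_spec("s", integer(0), purity = 1, fraction = 0.4)
  mix <- tracer_mixture(sp1, sp2)
  m_mix <- mfa13c:::tracer_emu_mid(mix, 1:2, nat13)
  m1 <- mfa13c:::tracer_emu_mid(tracer_spec("s", 1:2, 0.99), 1:2, nat13)
  m2 <- mfa13c:::tracer_emu_mid(tracer_spec("s", integer(0), 1), 1:2, nat13)
  expect_equal(m_mix, 0.6 * m1 + 0.4 * m2, tolerance = 1e-12)
})
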