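# Toy fixture networks built in code (shared across test files).

toy_model <- function(mets, rxns, mixing = list()) {
  met_df <- do.call(rbind, lapply(mets, function(m) {
    data.frame(id = m[[1]], compartment = m[[2]], carbons = as.integer(m[[3]]),
               symmetric = as.integer(m[[4]]), balanced = as.integer(m[[5]]),
               stringsAsFactors = FALSE)
  }))
  rxn_df <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r[[1]], equation = r[[2]], reversible = as.integer(r[[3]]),
               lower = r[[4]], upper = r[[5]], stringsAsFactors = FALSE)
  }))
  model_from_tables(rxn_df, met_df, mixing)
}

# Linear chain: in (2C) -> a -> b -> out
chain_model <- function() {
  toy_model(
    mets = list(list("in_e", "extracellular", 2, 0, 0),
                list("a", "cytosol", 2, 0, 1),
                list("b", "cytosol", 2, 0, 1),
                list("out_e", "extracellular", 2, 0, 0)),
    rxns = list(list("UP", "in_e (ab) --> a (ab)", 0, 0, 100),
                list("AB", "a (ab) --> b (ab)", 0, 0, 100),
                list("SEC", "b (ab) --> out_e (ab)", 0, 0, 100)))
}

# Diamond: in -> a; a -> b -> d; a -> c -> d; d -> out (1 free flux)
diamond_model <- function() {
  toy_model(
    mets = list(list("in_e", "extracellular", 2, 0, 0),
                list("a", "cytosol", 2, 0, 1),
                list("b", "cytosol", 2, 0, 1),
                list("c", "cytosol", 2, 0, 1),
                list("d", "cytosol", 2, 0, 1),
                list("out_e", "extracellular", 2, 0, 0)),
    rxns = list(list("UP", "in_e (ab) --> a (ab)", 0, 0, 100),
                list("AB", "a (ab) --> b (ab)", 0, 0, 100),
                list("AC", "a (ab) --> c (ab)", 0, 0, 100),
                list("BD", "b (ab) --> d (ab)", 0, 0, 100),
                list("CD", "c (ab) --> d (ba)", 0, 0, 100),
                list("OUT", "d (ab) --> out_e (ab)", 0, 0, 100)))
}

# Minimal TCA loop with symmetric succinate/fumarate and reversible FH.
toy_tca_model <- function(symmetric = TRUE) {
  s <- as.integer(symmetric)
  toy_model(
    mets = list(list("accoa_e", "extracellular", 2, 0, 0),
                list("co2_x", "extracellular", 1, 0, 0),
                list("oaa", "mitochondria", 4, 0, 1),
                list("cit", "mitochondria", 6, 0, 1),
                list("akg", "mitochondria", 5, 0, 1),
                list("suc", "mitochondria", 4, s, 1),
                list("fum", "mitochondria", 4, s, 1),
                list("mal", "mitochondria", 4, 0, 1)),
    rxns = list(
      list("CS", "oaa (abcd) + accoa_e (ef) --> cit (dcbfea)", 0, 0, 100),
      list("IDH", "cit (abcdef) --> akg (abcde) + co2_x (f)", 0, 0, 100),
      list("AKGDH", "akg (abcde) --> suc (bcde) + co2_x (a)", 0, 0, 100),
      list("SDH", "suc (abcd) --> fum (abcd)", 0, 0, 100),
      list("FH", "fum (abcd) --> mal (abcd)", 1, -100, 100),
      list("MDH", "mal (abcd) --> oaa (abcd)", 0, 0, 100)))
}

toy_tca_fluxes <- function(model, v = 1, fh_xch = 0.5) {
  flux_vector(model,
              net = c(CS = v, IDH = v, AKGDH = v, SDH = v, FH = v, MDH = v),
              xch = c(FH = fh_xch))
}

# Condensation/split network (transketolase-like carbon shuffling).
condense_model <- function() {
  toy_model(
    mets = list(list("x_e", "extracellular", 2, 0, 0),
                list("y_e", "extracellular", 3, 0, 0),
                list("a", "cytosol", 2, 0, 1),
                list("b", "cytosol", 3, 0, 1),
                list("d", "cytosol", 5, 0, 1),
                list("p_e", "extracellular", 2, 0, 0),
                list("q_e", "extracellular", 3, 0, 0)),
    rxns = list(
      list("UX", "x_e (ab) --> a (ab)", 0, 0, 100),
      list("UY", "y_e (abc) --> b (abc)", 0, 0, 100),
      list("CON", "a (ab) + b (cde) --> d (acebd)", 0, 0, 100),
      list("SPL", "d (abcde) --> p_e (db) + q_e (ace)", 0, 0, 100)))
}

# Reversible pair with a drain: in -> a <-> b -> out.
reversible_model <- function() {
  toy_model(
    mets = list(list("in_e", "extracellular", 3, 0, 0),
                list("a", "cytosol", 3, 0, 1),
                list("b", "cytosol", 3, 0, 1),
                list("out_e", "extracellular", 3, 0, 0)),
    rxns = list(list("UP", "in_e (abc) --> a (abc)", 0, 0, 100),
                list("AB", "a (abc) --> b (abc)", 1, -100, 100),
                list("OUT", "b (abc) --> out_e (abc)", 0, 0, 100)))
}

# Two-substrate dilution network with a mixing pool over two pools.
dilution_model <- function() {
  toy_model(
    mets = list(list("s1_e", "extracellular", 2, 0, 0),
                list("s2_e", "extracellular", 2, 0, 0),
                list("a1", "cytosol", 2, 0, 1),
                list("a2", "mitochondria", 2, 0, 1),
                list("out_e", "extracellular", 2, 0, 0),
                list("a_mix", "mixing", 2, 0, 0)),
    rxns = list(list("U1", "s1_e (ab) --> a1 (ab)", 0, 0, 100),
                list("T12", "a1 (ab) --> a2 (ab)", 1, -100, 100),
                list("U2", "s2_e (ab) --> a2 (ab)", 0, 0, 100),
                list("O2", "a2 (ab) --> out_e (ab)", 0, 0, 100)),
    mixing = list(a_mix = c("a1", "a2")))
}

zero_c13_table <- function() {
  tab <- default_abundance_table()
  tab$C <- c(1, 0)
  tab
}
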