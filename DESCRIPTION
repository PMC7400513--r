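Package: mfa13c
Title: Steady-State 13C Metabolic Flux Analysis with EMU Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stationary 13C metabolic flux analysis of cultured
    mammalian cells: a compartmentalized atom-mapped network model with a
    tab-separated model dialect, steady-state mass isotopomer distribution
    (MID) simulation by the elementary metabolite unit (EMU) method with a
    full-isotopomer brute-force oracle, natural isotope abundance correction
    for derivatized GC-MS fragments, extracellular uptake/secretion rate
    regression with first-order degradation, weighted least-squares flux
    fitting of parallel labelling experiments with chi-squared model
    validation and grid-search (profile likelihood) confidence intervals,
    and NADH/NADPH/FADH2/ATP cofactor accounting with pathway attribution.
    Includes a synthetic-data generator that emulates a paired study of
    parental and fumarate hydratase-diminished cells so the whole pipeline
    can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
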