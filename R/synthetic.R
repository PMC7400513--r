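#' Load the curated reference network model
#'
#' Convenience loader for the central-carbon model shipped with the
#' package (glycolysis, oxidative PPP, compartmentalized TCA cycle with
#' dual mitochondrial pyruvate pools, glutaminolysis, proline synthesis,
#' mixing pools, lumped biomass drain).
#'
#' @return A `network_model`.
#' @export
reference_model <- function() {
  load_model(pkg_extdata("reference_model.tsv"),
             pkg_extdata("reference_metabolites.tsv"),
             pkg_extdata("reference_mixing.tsv"))
}

# Condition definitions: printed extracellular anchors plus internal-flux
# choices; growth 0.0343 / 0.0208 1/h, glutamine degradation 0.00345 1/h.
scenario_conditions <- function() {
  list(
    parental = list(
      mu = 0.0343, X0 = 0.8,
      anchors = c(HK = 578.8, GLNUP = 82.7, LDH = 1087.7, PYRX = 61.7,
                  ALAT = 17.1, PROX = 13.9, SERUP = 22.0, BIOMASS = 0.0343,
                  PPP1 = 60, PC = 8, GDH = 52.9),
      fh_ratio = 0.995,  # reverse/forward ~ 1.00
      extra_q = c(cysteine = -4.1, arginine = -8.7)),
    fhdim = list(
      mu = 0.0208, X0 = 1.0,
      anchors = c(HK = 533.5, GLNUP = 52.7, LDH = 1009.8, PYRX = 57.8,
                  ALAT = 19.4, PROX = 1.5, SERUP = 16.2, BIOMASS = 0.0208,
                  PPP1 = 55, PC = 8, GDH = 45.9),
      fh_ratio = 0.18,
      extra_q = c(cysteine = -3.3, arginine = -9.6))
  )
}

#' Build a paired parental / FH-diminished study scenario
#'
#' Ground truth for the synthetic study: per condition, a steady-state flux
#' vector anchored to the measured extracellular exchange fluxes (glucose
#' 578.8 vs 533.5, glutamine 82.7 vs 52.7, lactate 1087.7 vs 1009.8,
#' proline 13.9 vs 1.5 nmol/1e6 cells/h, ...), growth rates 0.0343 vs
#' 0.0208 1/h, a reduced FH reverse/forward flux ratio in the
#' FH-diminished condition, mixing-pool fractions, tracer definitions
#' (\[1,2-13C\]glucose 99%, \[U-13C\]glutamine 98%), quench times 24/29/32 h
#' and the measurement noise model (MID SD 0.01, concentration CV 2%).
#'
#' @param name Scenario name.
#' @param seed Seed stored with the scenario and used by its simulators.
#' @return A `scenario` object.
#' @export
make_scenario <- function(name = "paper_like", seed = 1L) {
  model <- reference_model()
  conds <- scenario_conditions()
  xch_base <- c(IDH = 5, MDH = 50, CITL = 5, MDHC = 20, MALT = 10, GDH = 30)
  mix <- list(pyr_mix = c(pyr_c = 0.70, pyr_m1 = 0.15, pyr_m2 = 0.15),
              mal_mix = c(mal_c = 0.30, mal_m = 0.70),
              cit_mix = c(cit_c = 0.40, cit_m = 0.60))
  conditions <- lapply(conds, function(cn) {
    param <- parameterize_model(model, fixed = cn$anchors)
    if (param$n_free != 0L) {
      stop("scenario anchors do not pin the flux space (", param$n_free,
           " free dimensions left)", call. = FALSE)
    }
    fl0 <- expand_fluxes(param)
    fh_net <- fl0$net[["FH"]]
    xch <- c(xch_base, FH = unname(cn$fh_ratio / (1 - cn$fh_ratio) * fh_net))
    fluxes <- flux_vector(model, fl0$net, xch = xch)
    c(cn, list(fluxes = fluxes, param = param))
  })

  # Medium amounts: DMEM-like 20 mM glucose, 2 mM glutamine in a 4 mL dish;
  # nmol = mM * mL * 1000.
  volume_ml <- 4
  mM <- c(glucose = 20, glutamine = 2, serine = 0.4, cysteine = 0.2,
          arginine = 0.4, lactate = 0, pyruvate = 0, alanine = 0,
          proline = 0)
  A0 <- mM * volume_ml * 1000

  structure(
    list(name = name, seed = as.integer(seed), model = model,
         conditions = conditions, mix = mix,
         tracers = list(
           glc = list(glc_e = tracer_spec("glc_e", c(1, 2), purity = 0.99)),
           gln = list(gln_e = tracer_spec("gln_e", 1:5, purity = 0.98))),
         quench_times = c(24, 29, 32),
         degradation = c(glutamine = 0.00345),
         mid_sd = 0.01, conc_cv = 0.02, soft_rel_sd = 0.05,
         A0 = A0, volume_ml = volume_ml,
         # network reaction carrying each measured exchange (sign: uptake < 0)
         exchange_map = c(glucose = "HK", glutamine = "GLNUP",
                          serine = "SERUP", lactate = "LDH",
                          pyruvate = "PYRX", alanine = "ALAT",
                          proline = "PROX")),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d conditions, seed %d>\n", x$name,
              length(x$conditions), x$seed))
  invisible(x)
}

# Signed specific exchange rate q for a measured metabolite in a condition.
scenario_q <- function(scenario, cond_name, metabolite) {
  cn <- scenario$conditions[[cond_name]]
  if (metabolite %in% names(scenario$exchange_map)) {
    rxn <- scenario$exchange_map[[metabolite]]
    v <- cn$fluxes$net[[rxn]]
    if (metabolite %in% c("glucose", "glutamine", "serine")) -v else v
  } else {
    cn$extra_q[[metabolite]]
  }
}

#' Simulate growth, concentration, and cell-free time courses
#'
#' Cell counts grow exponentially at the condition's growth rate;
#' extracellular amounts follow [amount_model()] with the scenario's signed
#' exchange rates and the glutamine degradation constant; a cell-free
#' glutamine series decays at the degradation rate alone. Multiplicative
#' Gaussian noise (CV 2% by default) is applied per observation; negative
#' values are clipped to zero and flagged.
#'
#' @param scenario A [make_scenario()] object.
#' @param times Sampling times (h).
#' @param n_rep Replicates per time point.
#' @param seed Seed (defaults to the scenario's).
#' @return Data frame: `condition`, `metabolite`, `kind`, `replicate`,
#'   `time`, `value`, `clipped`.
#' @export
simulate_timecourses <- function(scenario, times = seq(0, 40, by = 8),
                                 n_rep = 3L, seed = NULL) {
  seed <- seed %||% scenario$seed
  cv <- scenario$conc_cv
  mets <- names(scenario$A0)
  rows <- list()
  with_seed(seed, {
    for (cond_name in names(scenario$conditions)) {
      cn <- scenario$conditions[[cond_name]]
      for (r in seq_len(n_rep)) {
        counts <- cn$X0 * exp(cn$mu * times) *
          exp(stats::rnorm(length(times), sd = cv))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond_name, metabolite = "cells", kind = "cell_count",
          replicate = r, time = times, value = counts, clipped = FALSE,
          stringsAsFactors = FALSE)
      }
      for (met in mets) {
        q <- scenario_q(scenario, cond_name, met)
        k <- if (met %in% names(scenario$degradation))
          scenario$degradation[[met]] else 0
        truth <- amount_model(times, scenario$A0[[met]], q, cn$X0, cn$mu, k)
        for (r in seq_len(n_rep)) {
          val <- truth * (1 + stats::rnorm(length(times), sd = cv))
          clipped <- val < 0
          val[clipped] <- 0
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond_name, metabolite = met, kind = "concentration",
            replicate = r, time = times, value = val, clipped = clipped,
            stringsAsFactors = FALSE)
        }
      }
    }
    # Cell-free glutamine degradation series (condition-independent).
    for (r in seq_len(n_rep)) {
      truth <- scenario$A0[["glutamine"]] *
        exp(-scenario$degradation[["glutamine"]] * times)
      val <- pmax(truth * (1 + stats::rnorm(length(times), sd = cv)), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = "cell_free", metabolite = "glutamine",
        kind = "cell_free_concentration", replicate = r, time = times,
        value = val, clipped = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Simulate noisy raw and corrected MID measurements
#'
#' For each condition and tracer experiment: simulates backbone MIDs at the
#' ground-truth fluxes (tracer impurity included), convolves them with
#' natural abundance into raw derivatized-ion space, draws Gaussian noise
#' (SD `mid_sd` per mass) independently for each quench-time replicate,
#' renormalizes, corrects each replicate back to backbone space, and pools
#' replicates by the mean. Soft flux measurements (glucose uptake, lactate
#' secretion) receive seeded 5% relative noise; the other measured
#' extracellular fluxes are fixed at their true values.
#'
#' @param scenario A [make_scenario()] object.
#' @param fragments Fragment list (defaults to the shipped reference table).
#' @param n_rep Replicates per quench time.
#' @param mid_sd Assumed per-mass SD recorded in the measurement set
#'   (defaults to the scenario's 0.01).
#' @param noise_sd Actual Gaussian noise applied per raw mass (defaults to
#'   `mid_sd`; set 0 for noise-free measurements, which also makes the soft
#'   flux measurements exact).
#' @param seed Seed (defaults to the scenario's).
#' @return Named list per condition: `measurements` (a [measurement_set()]),
#'   `replicates` (per-replicate corrected MIDs for stationarity checks),
#'   `truth_backbone` (noise-free backbone MIDs).
#' @export
simulate_mid_measurements <- function(scenario, fragments = NULL,
                                      n_rep = 3L, mid_sd = NULL,
                                      noise_sd = NULL, seed = NULL) {
  fragments <- fragments %||% read_fragment_table()
  seed <- seed %||% scenario$seed
  mid_sd <- mid_sd %||% scenario$mid_sd
  noise_sd <- noise_sd %||% mid_sd
  model <- scenario$model
  emunet <- decompose_emu(model, fragments)
  cms <- lapply(fragments, build_correction_matrix)
  out <- list()
  with_seed(seed, {
    for (cond_name in names(scenario$conditions)) {
      cn <- scenario$conditions[[cond_name]]
      mid_rows <- list()
      rep_rows <- list()
      truth <- list()
      for (exp_id in names(scenario$tracers)) {
        backbone <- simulate_mids(emunet, cn$fluxes,
                                  scenario$tracers[[exp_id]], scenario$mix)
        truth[[exp_id]] <- backbone
        for (fr in fragments) {
          raw0 <- convolve_natural(backbone[[fr$id]], cms[[fr$id]])
          reps <- list()
          for (t_i in seq_along(scenario$quench_times)) {
            for (r in seq_len(n_rep)) {
              noisy <- raw0 + stats::rnorm(length(raw0), sd = noise_sd)
              noisy <- pmax(noisy, 0)
              noisy <- noisy / sum(noisy)
              corr <- as.numeric(correct_mid(noisy, cms[[fr$id]]))
              reps[[length(reps) + 1L]] <- corr
              rep_rows[[length(rep_rows) + 1L]] <- data.frame(
                experiment = exp_id, fragment = fr$id,
                time = scenario$quench_times[t_i], replicate = r,
                mass = seq_along(corr) - 1L, value = corr,
                stringsAsFactors = FALSE)
            }
          }
          pooled <- Reduce(`+`, reps) / length(reps)
          pooled <- pooled / sum(pooled)
          mid_rows[[length(mid_rows) + 1L]] <- data.frame(
            experiment = exp_id, fragment = fr$id,
            mass = seq_along(pooled) - 1L, mean = pooled, sd = mid_sd,
            stringsAsFactors = FALSE)
        }
      }
      soft_true <- c(HK = cn$fluxes$net[["HK"]], LDH = cn$fluxes$net[["LDH"]])
      soft_meas <- if (noise_sd > 0) {
        soft_true * (1 + stats::rnorm(2, sd = scenario$soft_rel_sd))
      } else soft_true
      soft <- data.frame(reaction = names(soft_true), value = soft_meas,
                         rel_sd = scenario$soft_rel_sd,
                         stringsAsFactors = FALSE)
      fixed <- c(GLNUP = cn$fluxes$net[["GLNUP"]],
                 PYRX = cn$fluxes$net[["PYRX"]],
                 ALAT = cn$fluxes$net[["ALAT"]],
                 PROX = cn$fluxes$net[["PROX"]],
                 SERUP = cn$fluxes$net[["SERUP"]],
                 BIOMASS = cn$fluxes$net[["BIOMASS"]])
      out[[cond_name]] <- list(
        measurements = measurement_set(do.call(rbind, mid_rows), soft, fixed),
        replicates = do.call(rbind, rep_rows),
        truth_backbone = truth)
    }
  })
  out
}
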