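#' Published comparative tables
#'
#' Readers for the printed extracellular-flux and ATP-ledger tables shipped
#' as package data; these are the inputs to the comparative reporting
#' arithmetic ([percent_change()], [flux_ratio()], [ledger_report()]).
#'
#' @param path Optional override path.
#' @return A data frame.
#' @export
read_published_exchange_fluxes <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("published_exchange_fluxes.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_published_exchange_fluxes
#' @export
read_published_atp_ledger <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("published_atp_ledger.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Comparative extracellular flux table
#'
#' Adds the integer percent-change column (`100 * (fhdim - parental) /
#' parental`) to a two-condition exchange-flux table and computes the
#' lactate/glucose flux ratio per condition.
#'
#' @param fluxes Data frame with columns `metabolite`, `direction`,
#'   `parental`, `fhdim` (flux magnitudes), as from
#'   [read_published_exchange_fluxes()] or [fit_all_exchange_rates()].
#' @return List with `table` (the input plus `percent_change`) and
#'   `lactate_glucose_ratio` (named vector, 2 decimals).
#' @export
exchange_table <- function(fluxes) {
  fluxes$percent_change <- vapply(seq_len(nrow(fluxes)), function(i) {
    percent_change(fluxes$parental[i], fluxes$fhdim[i])
  }, 0)
  ratio <- c(parental = NA_real_, fhdim = NA_real_)
  if (all(c("lactate", "glucose") %in% fluxes$metabolite)) {
    lac <- fluxes[fluxes$metabolite == "lactate", ]
    glc <- fluxes[fluxes$metabolite == "glucose", ]
    ratio <- c(parental = flux_ratio(lac$parental, glc$parental),
               fhdim = flux_ratio(lac$fhdim, glc$fhdim))
  }
  list(table = fluxes, lactate_glucose_ratio = ratio)
}

#' Fit every exchange rate of a simulated (or measured) time-course set
#'
#' Per condition: growth rate from the cell counts, glutamine degradation
#' from the cell-free series, then one [fit_exchange_rate()] per metabolite
#' using the fitted growth rate and initial cell number.
#'
#' @param timecourses Tidy data frame as produced by
#'   [simulate_timecourses()] (`condition`, `metabolite`, `kind`,
#'   `replicate`, `time`, `value`).
#' @param n_boot,seed Bootstrap controls for the per-metabolite CIs.
#' @return List per condition: `mu` (growth fit), `rates` (data frame of
#'   per-metabolite results); plus `k_glutamine` (degradation fit).
#' @export
fit_all_exchange_rates <- function(timecourses, n_boot = 1000L, seed = 1L) {
  out <- list()
  cf <- timecourses[timecourses$kind == "cell_free_concentration" &
                      timecourses$metabolite == "glutamine", , drop = FALSE]
  k_gln <- if (nrow(cf) >= 3L) {
    fit_degradation_rate(time_course(cf$time[order(cf$replicate, cf$time)],
                                     cf$value[order(cf$replicate, cf$time)],
                                     cf$replicate[order(cf$replicate, cf$time)],
                                     kind = "cell_free_concentration"))$k
  } else 0
  for (cond in setdiff(unique(timecourses$condition), "cell_free")) {
    sub <- timecourses[timecourses$condition == cond, , drop = FALSE]
    cc <- sub[sub$kind == "cell_count", , drop = FALSE]
    ord <- order(cc$replicate, cc$time)
    growth <- fit_growth_rate(time_course(cc$time[ord], cc$value[ord],
                                          cc$replicate[ord],
                                          kind = "cell_count"))
    X0 <- exp(unname(stats::coef(growth$fit)[1]))
    mets <- unique(sub$metabolite[sub$kind == "concentration"])
    rates <- lapply(mets, function(met) {
      d <- sub[sub$metabolite == met & sub$kind == "concentration", ,
               drop = FALSE]
      ord <- order(d$replicate, d$time)
      k <- if (met == "glutamine") k_gln else 0
      res <- fit_exchange_rate(
        time_course(d$time[ord], d$value[ord], d$replicate[ord]),
        mu = growth$mu, X0 = X0, k = k, metabolite = met,
        n_boot = n_boot, seed = seed)
      data.frame(metabolite = met, direction = res$direction,
                 flux = res$flux, lb = res$ci[1], ub = res$ci[2],
                 q = res$q, stringsAsFactors = FALSE)
    })
    out[[cond]] <- list(mu = growth, X0 = X0,
                        rates = do.call(rbind, rates))
  }
  out$k_glutamine <- k_gln
  out
}

#' Run the whole pipeline on a synthetic study and report recovery
#'
#' Generates a paired parental/FH-diminished scenario, simulates time
#' courses and MID measurements, estimates extracellular rates, fits the
#' flux distribution per condition, and derives the comparative exchange
#' and ATP-ledger reports, together with per-flux recovery errors against
#' the generating ground truth.
#'
#' @param seed Seed for the scenario and every simulation stage.
#' @param options [fit_options()] for the flux fits (default uses 3 starts
#'   plus a data-informed warm start to keep runtime modest).
#' @param n_boot Bootstrap resamples for the extracellular CIs.
#' @return A list with `scenario`, `exo` (extracellular fits),
#'   `exchange` (comparative exchange-flux table), `fits`, `stationarity`,
#'   `ledgers`, `ledger_table` (comparative ATP table), and `recovery`
#'   (per-reaction true/fitted net fluxes).
#' @export
end_to_end <- function(seed = 1L, options = fit_options(n_starts = 3L,
                                                        seed = seed),
                       n_boot = 200L) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scen <- stage("scenario", make_scenario(seed = seed))
  tc <- stage("timecourses", simulate_timecourses(scen))
  exo <- stage("exoflux", fit_all_exchange_rates(tc, n_boot = n_boot,
                                                 seed = seed))
  mids <- stage("mids", simulate_mid_measurements(scen))
  fragments <- read_fragment_table()

  stat <- stage("stationarity", lapply(names(scen$conditions), function(cn) {
    reps <- mids[[cn]]$replicates
    assess_stationarity(data.frame(
      fragment = paste(reps$experiment, reps$fragment, sep = ":"),
      time = reps$time, replicate = reps$replicate, mass = reps$mass,
      value = reps$value, stringsAsFactors = FALSE))
  }))
  names(stat) <- names(scen$conditions)

  fits <- stage("mfa_fit", lapply(names(scen$conditions), function(cn) {
    prob <- mfa_problem(scen$model, fragments, scen$tracers,
                        mids[[cn]]$measurements, options)
    # Data-informed warm start: soft measurements pin glycolysis (about
    # 90% of glucose passes phosphofructokinase once a typical oxidative
    # PPP share is allowed for); other free fluxes start modest.
    init_free <- stats::setNames(numeric(prob$n_free), prob$free_ids)
    sm <- mids[[cn]]$measurements$soft
    for (r in prob$free_ids) {
      init_free[r] <- if (r %in% sm$reaction) sm$value[sm$reaction == r]
      else 20
    }
    if ("PFK" %in% prob$free_ids && "HK" %in% sm$reaction) {
      init_free["PFK"] <- 0.90 * sm$value[sm$reaction == "HK"]
    }
    init_fl <- tryCatch(
      expand_fluxes(prob$param, init_free, check_bounds = FALSE),
      error = function(e) NULL)
    fit_fluxes(prob, init = if (!is.null(init_fl))
      list(fluxes = init_fl) else NULL)
  }))
  names(fits) <- names(scen$conditions)

  exo_tab <- data.frame(
    metabolite = exo$parental$rates$metabolite,
    direction = exo$parental$rates$direction,
    parental = exo$parental$rates$flux,
    fhdim = exo$fhdim$rates$flux[match(exo$parental$rates$metabolite,
                                       exo$fhdim$rates$metabolite)],
    stringsAsFactors = FALSE)
  exchange <- stage("exchange_report", exchange_table(exo_tab))

  stoich <- read_cofactor_table(model = scen$model)
  ledgers <- stage("ledger", lapply(fits, function(f)
    atp_production(f$fluxes, stoich)))
  ledger_tab <- ledger_report(ledgers$parental, ledgers$fhdim)

  recovery <- do.call(rbind, lapply(names(scen$conditions), function(cn) {
    truth <- scen$conditions[[cn]]$fluxes$net
    fitted <- fits[[cn]]$fluxes$net
    data.frame(condition = cn, reaction = names(truth),
               truth = unname(truth), fitted = unname(fitted[names(truth)]),
               abs_error = abs(unname(fitted[names(truth)] - truth)),
               stringsAsFactors = FALSE)
  }))

  list(scenario = scen, exo = exo, exchange = exchange, fits = fits,
       stationarity = stat, ledgers = ledgers, ledger_table = ledger_tab,
       recovery = recovery)
}
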