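#' Options controlling the flux fit
#'
#' @param n_starts Number of multistart launches (first start is the
#'   midpoint/warm start, the rest are seeded uniform draws).
#' @param seed RNG seed for the multistart draws.
#' @param maxit Iteration cap per start.
#' @param xch_scale Scale of the bounded exchange transform
#'   `xch = xch_scale * u / (1 - u)`, `u` in `[0, u_max]`.
#' @param u_max Upper bound of the exchange transform coordinate.
#' @param penalty Quadratic penalty weight for bound violations of dependent
#'   (non-free) fluxes.
#' @param count_mode Measurement counting convention for degrees of freedom;
#'   see [count_measurements()].
#' @return A `fit_options` list.
#' @export
fit_options <- function(n_starts = 20L, seed = 1L, maxit = 300L,
                        xch_scale = 100, u_max = 0.999, penalty = 1e6,
                        count_mode = "raw") {
  stopifnot(n_starts >= 1L)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), xch_scale = xch_scale,
                 u_max = u_max, penalty = penalty, count_mode = count_mode),
            class = "fit_options")
}

#' Assemble a flux-fitting problem
#'
#' Joint fit of parallel labelling experiments: a single parameter vector
#' (free net fluxes, bounded exchange coordinates, mixing fractions) is
#' scored against every experiment's corrected MIDs plus the soft flux
#' measurements. Hard flux constraints enter the parameterization.
#'
#' @param model A `network_model`.
#' @param fragments Named list of [fragment_spec()]s (the fitted fragments).
#' @param experiments Named list: experiment id -> named list of
#'   [tracer_spec()]s keyed by substrate.
#' @param measurements A [measurement_set()].
#' @param options A [fit_options()].
#' @return An `mfa_problem`.
#' @export
mfa_problem <- function(model, fragments, experiments, measurements,
                        options = fit_options()) {
  param <- parameterize_model(model, fixed = measurements$fixed)
  emunet <- decompose_emu(model, fragments)
  rev_ids <- reversible_reactions(model)
  pools <- names(model$mixing_rules)
  pool_sizes <- vapply(model$mixing_rules, length, 0L)

  # Parameter layout: [free nets | exchange u | mixing sticks]
  free_ids <- param$free_ids
  n_free <- length(free_ids)
  n_rev <- length(rev_ids)
  n_mix <- sum(pmax(pool_sizes - 1L, 0L))
  lower <- c(vapply(free_ids, function(r) model$reactions[[r]]$lower, 0),
             rep(0, n_rev), rep(0, n_mix))
  upper <- c(vapply(free_ids, function(r) model$reactions[[r]]$upper, 0),
             rep(options$u_max, n_rev), rep(1, n_mix))
  par_names <- c(free_ids, paste0("xch.", rev_ids),
                 unlist(lapply(pools, function(p) {
                   if (pool_sizes[[p]] < 2L) character(0) else
                     paste0("mix.", p, ".", seq_len(pool_sizes[[p]] - 1L))
                 })) %||% character(0))

  structure(
    list(model = model, fragments = fragments, experiments = experiments,
         measurements = measurements, options = options, param = param,
         emunet = emunet, rev_ids = rev_ids, pools = pools,
         pool_sizes = pool_sizes, free_ids = free_ids,
         n_free = n_free, n_rev = n_rev, n_mix = n_mix,
         lower = lower, upper = upper, par_names = par_names,
         n_params = n_free + n_rev + n_mix),
    class = "mfa_problem"
  )
}

#' @export
print.mfa_problem <- function(x, ...) {
  cat(sprintf("<mfa_problem: %d parameters (%d free nets, %d exchanges, %d mixing), %d experiments>\n",
              x$n_params, x$n_free, x$n_rev, x$n_mix, length(x$experiments)))
  invisible(x)
}

# Decode a parameter vector into fluxes + mixing fractions.
decode_theta <- function(problem, theta) {
  n_free <- problem$n_free; n_rev <- problem$n_rev
  free_values <- stats::setNames(theta[seq_len(n_free)], problem$free_ids)
  u <- theta[n_free + seq_len(n_rev)]
  xch <- stats::setNames(problem$options$xch_scale * u / (1 - u),
                         problem$rev_ids)
  mix <- list()
  off <- n_free + n_rev
  for (p in problem$pools) {
    m <- problem$pool_sizes[[p]]
    if (m < 2L) next
    sticks <- theta[off + seq_len(m - 1L)]
    off <- off + m - 1L
    fr <- numeric(m)
    rest <- 1
    for (i in seq_len(m - 1L)) {
      fr[i] <- rest * sticks[i]
      rest <- rest - fr[i]
    }
    fr[m] <- rest
    mix[[p]] <- stats::setNames(fr, problem$model$mixing_rules[[p]])
  }
  fluxes <- expand_fluxes(problem$param, free_values, xch = xch,
                          check_bounds = FALSE)
  list(fluxes = fluxes, mix = mix, free_values = free_values)
}

# Encode fluxes + mixing fractions back into a parameter vector (used for
# warm starts and for re-parameterized profile fits).
encode_theta <- function(problem, fluxes, mix = list()) {
  u <- fluxes$xch[problem$rev_ids] /
    (problem$options$xch_scale + fluxes$xch[problem$rev_ids])
  u <- pmin(pmax(u, 0), problem$options$u_max)
  sticks <- numeric(0)
  for (p in problem$pools) {
    m <- problem$pool_sizes[[p]]
    if (m < 2L) next
    fr <- mix[[p]]
    if (is.null(fr)) fr <- rep(1 / m, m)
    s <- numeric(m - 1L)
    rest <- 1
    for (i in seq_len(m - 1L)) {
      s[i] <- if (rest > 1e-12) fr[i] / rest else 0
      rest <- rest - fr[i]
    }
    sticks <- c(sticks, pmin(pmax(s, 0), 1))
  }
  theta <- c(unname(fluxes$net[problem$free_ids]), unname(u), sticks)
  pmin(pmax(theta, problem$lower), problem$upper)
}

#' Weighted residual sum of squares of a candidate flux solution
#'
#' `RSS = sum(((sim - meas) / sd)^2)` over every fitted MID mass of every
#' tracer experiment, plus `((v - value) / (rel_sd * value))^2` for each
#' soft flux measurement. Simulation honours parallel labelling: one EMU
#' solve per experiment, a single flux vector.
#'
#' @param problem An `mfa_problem`.
#' @param fluxes A `flux_vector` (or `NULL` to decode from `theta`).
#' @param mix Mixing fractions (named list of named fraction vectors).
#' @param theta Raw parameter vector (alternative entry point).
#' @param penalized Include the bound-violation penalty (used by the
#'   optimizer; `FALSE` reports the pure measurement RSS).
#' @return The scalar RSS.
#' @export
residual_ss <- function(problem, fluxes = NULL, mix = list(), theta = NULL,
                        penalized = FALSE) {
  pen <- 0
  if (is.null(fluxes)) {
    dec <- decode_theta(problem, theta)
    fluxes <- dec$fluxes
    mix <- dec$mix
  }
  if (penalized && length(fluxes$violations)) {
    viol <- vapply(problem$model$reactions, function(rx) {
      v <- fluxes$net[rx$id]
      max(0, rx$lower - v, v - rx$upper)
    }, 0)
    pen <- problem$options$penalty * sum(viol^2)
  }
  nat13 <- natural_c13_fraction()
  fv <- directed_flux_values(problem$model, fluxes)
  rss <- 0
  mids_df <- problem$measurements$mids
  for (exp_id in names(problem$experiments)) {
    sim <- tryCatch(
      assemble_fragment_mids(
        problem$emunet,
        emu_solve(problem$emunet, fv, problem$experiments[[exp_id]], nat13),
        mix),
      error = function(e) stop("simulating experiment ", exp_id, ": ",
                               conditionMessage(e), call. = FALSE))
    sel <- mids_df$experiment == exp_id
    sub <- mids_df[sel, , drop = FALSE]
    for (fr_id in unique(sub$fragment)) {
      rows <- sub[sub$fragment == fr_id, , drop = FALSE]
      s <- sim[[fr_id]]
      if (is.null(s)) stop("no simulated MID for fragment ", fr_id,
                           call. = FALSE)
      rss <- rss + sum(((s[rows$mass + 1L] - rows$mean) / rows$sd)^2)
    }
  }
  soft <- problem$measurements$soft
  if (!is.null(soft)) {
    for (i in seq_len(nrow(soft))) {
      v <- fluxes$net[soft$reaction[i]]
      rss <- rss + ((v - soft$value[i]) / (soft$rel_sd[i] * soft$value[i]))^2
    }
  }
  unname(rss + pen)
}

#' Fit metabolic fluxes by multistart weighted least squares
#'
#' Bound-constrained quasi-Newton minimization (`nlminb`) of
#' [residual_ss()] from multiple seeded starting points; deterministic for
#' a given seed.
#'
#' @param problem An `mfa_problem`.
#' @param init Optional warm start: a list with `fluxes` (a `flux_vector`)
#'   and optionally `mix`, or a raw parameter vector.
#' @return An `mfa_fit` with the best flux vector, mixing fractions, RSS,
#'   degrees of freedom, chi-squared threshold and verdict, and the
#'   per-start RSS trace.
#' @export
fit_fluxes <- function(problem, init = NULL) {
  opts <- problem$options
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- if (is.numeric(init)) init else
      encode_theta(problem, init$fluxes, init$mix %||% list())
  }
  n_draw <- opts$n_starts - length(starts)
  if (n_draw > 0) {
    # Cap random net-flux draws at a physiological scale (soft measurements
    # set it when present) so starts land in a simulable region.
    soft <- problem$measurements$soft
    cap <- if (!is.null(soft) && nrow(soft)) 2 * max(abs(soft$value)) else 500
    draws <- with_seed(opts$seed, {
      lapply(seq_len(n_draw), function(i) {
        lo <- problem$lower; hi <- pmin(problem$upper, cap)
        th <- lo + stats::runif(length(lo)) * (hi - lo)
        ui <- problem$n_free + seq_len(problem$n_rev)
        th[ui] <- stats::runif(problem$n_rev, 0, 0.7)
        mi <- problem$n_free + problem$n_rev + seq_len(problem$n_mix)
        th[mi] <- stats::runif(problem$n_mix, 0.2, 0.8)
        th
      })
    })
    starts <- c(starts, draws)
  }
  objective <- function(th) {
    tryCatch(residual_ss(problem, theta = th, penalized = TRUE),
             error = function(e) 1e12)
  }
  results <- lapply(seq_along(starts), function(i) {
    th0 <- pmin(pmax(starts[[i]], problem$lower), problem$upper)
    res <- tryCatch(
      stats::nlminb(th0, objective,
                    lower = problem$lower, upper = problem$upper,
                    scale = 1 / pmax(abs(th0), 0.1),
                    control = list(iter.max = opts$maxit,
                                   eval.max = 10L * opts$maxit)),
      error = function(e) list(objective = Inf, par = th0, message =
                                 conditionMessage(e), convergence = 99L))
    res
  })
  objs <- vapply(results, `[[`, 0, "objective")
  # objectives >= 1e11 sit on the non-simulable penalty plateau
  if (all(!is.finite(objs) | objs >= 1e11)) {
    stop("all ", length(starts), " starts failed to converge to a ",
         "simulable flux solution", call. = FALSE)
  }
  objs[objs >= 1e11] <- Inf
  best <- results[[which.min(objs)]]
  # Polish: one restart from the incumbent with scaling recomputed there;
  # PORT's fixed diagonal scaling is start-dependent and a rescaled restart
  # regularly escapes premature convergence.
  for (round in 1:5) {
    pol <- tryCatch(
      stats::nlminb(best$par, objective,
                    lower = problem$lower, upper = problem$upper,
                    scale = 1 / pmax(abs(best$par), 0.1),
                    control = list(iter.max = opts$maxit,
                                   eval.max = 10L * opts$maxit)),
      error = function(e) NULL)
    if (is.null(pol) ||
        pol$objective >= best$objective - 1e-6 * (1 + abs(best$objective))) {
      break
    }
    best <- pol
  }
  dec <- decode_theta(problem, best$par)
  rss <- residual_ss(problem, fluxes = dec$fluxes, mix = dec$mix)
  n_meas <- count_measurements(problem$measurements, opts$count_mode)
  dof <- n_meas - problem$n_params
  structure(
    list(problem = problem, theta = best$par, fluxes = dec$fluxes,
         mix = dec$mix, rss = rss, penalized_rss = best$objective,
         n_measurements = n_meas, n_parameters = problem$n_params,
         dof = dof, start_rss = objs, convergence = best$convergence),
    class = "mfa_fit"
  )
}

#' @export
print.mfa_fit <- function(x, ...) {
  g <- goodness_of_fit(x)
  cat(sprintf("<mfa_fit: RSS %.3f on %d dof (chi2[0.95] = %.2f) -> %s; %d start(s)>\n",
              x$rss, x$dof, g$threshold, ifelse(g$pass, "PASS", "FAIL"),
              length(x$start_rss)))
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' The fit is statistically acceptable at level `alpha` when the minimized
#' RSS does not exceed the upper `1 - alpha` quantile of the chi-squared
#' distribution with the fit's degrees of freedom.
#'
#' @param fit An `mfa_fit` (or a list with `rss` and `dof`).
#' @param alpha Test level (default 0.05).
#' @return List with `pass`, `rss`, `dof`, `threshold`.
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  if (fit$dof <= 0) {
    stop("model is overparameterized: dof = ", fit$dof, call. = FALSE)
  }
  threshold <- stats::qchisq(1 - alpha, df = fit$dof)
  list(pass = fit$rss <= threshold, rss = fit$rss, dof = fit$dof,
       threshold = threshold)
}
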