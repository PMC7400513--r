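# Generic profile-likelihood interval by outward grid search + bisection.
# `profile_rss(value)` must return the minimized RSS with the parameter of
# interest pinned at `value` (NA = re-optimization failure; the point is
# skipped with a warning). The boundary in each direction is where the
# profile crosses `rss_best + qchisq(level, 1)`.
profile_interval <- function(profile_rss, best, rss_best, level = 0.95,
                             step = NULL, rel_step = 0.05, min_step = 1e-3,
                             max_steps = 40L, rel_tol = 1e-3,
                             lower_limit = -Inf, upper_limit = Inf) {
  crit <- rss_best + stats::qchisq(level, df = 1)
  if (is.null(step)) step <- max(rel_step * abs(best), min_step)

  scan_dir <- function(sgn) {
    limit <- if (sgn > 0) upper_limit else lower_limit
    x_in <- best
    h <- step
    for (i in seq_len(max_steps)) {
      x <- x_in + sgn * h
      hit_limit <- (sgn > 0 && x >= limit) || (sgn < 0 && x <= limit)
      if (hit_limit) x <- limit
      r <- profile_rss(x)
      if (is.na(r)) {
        warning("profile re-optimization failed at ", format(x),
                "; grid point skipped")
        if (hit_limit) return(NA_real_)
        h <- h * 2
        next
      }
      if (r > crit) {
        # bracket [x_in, x]; bisection refine
        lo <- x_in; hi <- x
        tol <- max(rel_tol * abs(best), rel_tol * step)
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          rm_ <- profile_rss(mid)
          if (is.na(rm_)) {
            warning("profile re-optimization failed at ", format(mid),
                    "; grid point skipped")
            break
          }
          if (rm_ > crit) hi <- mid else lo <- mid
        }
        return((lo + hi) / 2)
      }
      x_in <- x
      if (hit_limit) return(NA_real_)  # still below threshold at the limit
      h <- h * 2
    }
    NA_real_  # never crossed within the scan range -> not determined
  }

  lower <- scan_dir(-1)
  upper <- scan_dir(+1)
  list(lower = lower, upper = upper, level = level, best = best,
       threshold = crit)
}

#' Grid-search (profile likelihood) confidence interval for a flux
#'
#' Pins the target quantity across an outward grid, re-optimizes every other
#' parameter at each grid point (warm-started from the neighbouring
#' solution), and brackets the RSS threshold `RSS_best + chi2(level, 1)` by
#' bisection. Directions in which the profile never crosses the threshold
#' are reported as `NA` bounds ("not determined").
#'
#' @param fit An `mfa_fit`.
#' @param reaction Reaction id.
#' @param what `"net"` for the net flux, `"xch"` for the exchange flux of a
#'   reversible reaction.
#' @param level Confidence level.
#' @param maxit Iteration cap for each pinned re-optimization.
#' @param ... Scan controls passed to the internal profiler (`rel_step`,
#'   `min_step`, `max_steps`, `rel_tol`).
#' @return A `flux_ci`: list with `reaction`, `what`, `best`, `lower`,
#'   `upper` (NA = not determined), `level`.
#' @export
grid_search_ci <- function(fit, reaction, what = c("net", "xch"),
                           level = 0.95, maxit = 150L, ...) {
  what <- match.arg(what)
  problem <- fit$problem
  model <- problem$model
  if (!reaction %in% names(model$reactions)) {
    stop("unknown reaction ", reaction, call. = FALSE)
  }
  if (what == "xch" && !reaction %in% problem$rev_ids) {
    stop(reaction, " is irreversible; no exchange flux", call. = FALSE)
  }

  if (what == "net") {
    if (reaction %in% names(problem$measurements$fixed)) {
      v <- problem$measurements$fixed[[reaction]]
      return(structure(list(reaction = reaction, what = what, best = v,
                            lower = v, upper = v, level = level,
                            collapsed = TRUE), class = "flux_ci"))
    }
    # Re-parameterize so the target reaction is a free coordinate.
    param_r <- parameterize_model(model, fixed = problem$measurements$fixed,
                                  prefer_free = reaction)
    if (!reaction %in% param_r$free_ids) {
      # Fully determined by constraints + stoichiometry: CI collapses.
      v <- fit$fluxes$net[[reaction]]
      return(structure(list(reaction = reaction, what = what, best = v,
                            lower = v, upper = v, level = level,
                            collapsed = TRUE), class = "flux_ci"))
    }
    prob_r <- problem
    prob_r$param <- param_r
    prob_r$free_ids <- param_r$free_ids
    prob_r$lower[seq_len(prob_r$n_free)] <-
      vapply(param_r$free_ids, function(r) model$reactions[[r]]$lower, 0)
    prob_r$upper[seq_len(prob_r$n_free)] <-
      vapply(param_r$free_ids, function(r) model$reactions[[r]]$upper, 0)
    pin_idx <- match(reaction, param_r$free_ids)
    best_val <- fit$fluxes$net[[reaction]]
    lim_lo <- model$reactions[[reaction]]$lower
    lim_hi <- model$reactions[[reaction]]$upper
  } else {
    prob_r <- problem
    pin_idx <- problem$n_free + match(reaction, problem$rev_ids)
    u_best <- fit$theta[pin_idx]
    best_val <- fit$fluxes$xch[[reaction]]
    lim_lo <- 0
    lim_hi <- problem$options$u_max
  }

  theta0 <- encode_theta(prob_r, fit$fluxes, fit$mix)
  warm <- new.env(parent = emptyenv())
  warm$theta <- theta0

  refit_pinned <- function(value) {
    pin <- if (what == "xch") value else value
    th <- warm$theta
    th[pin_idx] <- pin
    lo <- prob_r$lower; hi <- prob_r$upper
    lo[pin_idx] <- pin; hi[pin_idx] <- pin
    obj <- function(t) {
      tryCatch(residual_ss(prob_r, theta = t, penalized = TRUE),
               error = function(e) 1e12)
    }
    th_start <- pmin(pmax(th, lo), hi)
    res <- tryCatch(
      stats::nlminb(th_start, obj,
                    lower = lo, upper = hi,
                    scale = 1 / pmax(abs(th_start), 0.1),
                    control = list(iter.max = maxit, eval.max = 4L * maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) return(NA_real_)
    # keep the warm start only when the pinned solution is simulable;
    # penalty-plateau points would poison subsequent warm starts
    if (res$objective < 1e11) warm$theta <- res$par
    res$objective
  }

  if (what == "xch") {
    # Profile on the bounded u coordinate, report on the xch scale.
    prof <- profile_interval(refit_pinned, best = u_best,
                             rss_best = fit$rss, level = level,
                             step = 0.05, min_step = 0.01,
                             lower_limit = lim_lo, upper_limit = lim_hi, ...)
    to_x <- function(u) if (is.na(u)) NA_real_ else
      prob_r$options$xch_scale * u / (1 - u)
    lower <- to_x(prof$lower); upper <- to_x(prof$upper)
  } else {
    prof <- profile_interval(refit_pinned, best = best_val,
                             rss_best = fit$rss, level = level,
                             lower_limit = lim_lo, upper_limit = lim_hi, ...)
    lower <- prof$lower; upper <- prof$upper
  }
  structure(list(reaction = reaction, what = what, best = best_val,
                 lower = lower, upper = upper, level = level,
                 collapsed = FALSE),
            class = "flux_ci")
}

#' @export
print.flux_ci <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "ND" else sprintf("%.2f", v)
  cat(sprintf("%s %s flux %.2f, %d%% CI [%s, %s]\n", x$reaction, x$what,
              x$best, round(100 * x$level), fmt(x$lower), fmt(x$upper)))
  invisible(x)
}

#' Significance of a flux difference between two conditions
#'
#' A difference is called significant exactly when the two confidence
#' intervals do not overlap; touching (closed-interval) endpoints count as
#' overlap, i.e. not significant. A not-determined bound on the side that
#' would decide the comparison makes the call indeterminate.
#'
#' @param ci_a,ci_b `flux_ci` objects (or lists with `lower`, `upper`,
#'   `best`).
#' @return List with `significant` (TRUE/FALSE/NA), `direction`
#'   (`"increased"`/`"decreased"`/`NA`, the change from condition A to B).
#' @export
compare_cis <- function(ci_a, ci_b) {
  a_lo <- ci_a$lower; a_hi <- ci_a$upper
  b_lo <- ci_b$lower; b_hi <- ci_b$upper
  direction <- if (is.na(ci_a$best %||% NA) || is.na(ci_b$best %||% NA)) {
    NA_character_
  } else if (ci_b$best > ci_a$best) "increased" else
    if (ci_b$best < ci_a$best) "decreased" else "unchanged"
  # Disjoint iff one interval lies strictly above the other.
  a_below <- if (!is.na(a_hi) && !is.na(b_lo)) a_hi < b_lo else NA
  b_below <- if (!is.na(b_hi) && !is.na(a_lo)) b_hi < a_lo else NA
  significant <- if (isTRUE(a_below) || isTRUE(b_below)) TRUE
  else if (identical(a_below, FALSE) && identical(b_below, FALSE)) FALSE
  else NA
  list(significant = significant,
       direction = if (isTRUE(significant)) direction else direction)
}

#' Compare two fitted conditions reaction by reaction
#'
#' @param fit_a,fit_b `mfa_fit` objects for the two conditions.
#' @param reactions Reaction ids to compare.
#' @param what `"net"` or `"xch"`.
#' @param ... Passed to [grid_search_ci()].
#' @return Data frame: reaction, best fluxes, CI bounds, significance and
#'   direction (condition A -> condition B).
#' @export
compare_conditions <- function(fit_a, fit_b, reactions, what = "net", ...) {
  rows <- lapply(reactions, function(r) {
    ca <- grid_search_ci(fit_a, r, what = what, ...)
    cb <- grid_search_ci(fit_b, r, what = what, ...)
    cmp <- compare_cis(ca, cb)
    data.frame(reaction = r, best_a = ca$best, lower_a = ca$lower,
               upper_a = ca$upper, best_b = cb$best, lower_b = cb$lower,
               upper_b = cb$upper, significant = cmp$significant,
               direction = cmp$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
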