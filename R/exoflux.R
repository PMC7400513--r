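#' Time-course container
#'
#' @param times Sampling times in hours (strictly increasing within a
#'   replicate).
#' @param values Concentrations (nmol per dish) or cell counts (1e6 cells).
#' @param replicate Replicate labels (optional).
#' @param kind One of `cell_count`, `concentration`, `cell_free_concentration`.
#' @return A `time_course` data frame.
#' @export
time_course <- function(times, values, replicate = 1L,
                        kind = c("concentration", "cell_count",
                                 "cell_free_concentration")) {
  kind <- match.arg(kind)
  if (any(values < 0)) stop("time-course values must be nonnegative",
                            call. = FALSE)
  df <- data.frame(time = times, value = values, replicate = replicate,
                   stringsAsFactors = FALSE)
  for (r in unique(df$replicate)) {
    tt <- df$time[df$replicate == r]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("times must be strictly increasing within a replicate",
           call. = FALSE)
    }
  }
  attr(df, "kind") <- kind
  class(df) <- c("time_course", class(df))
  df
}

#' Specific growth rate from a semi-logarithmic fit
#'
#' Linear regression of `ln(count)` on time; the slope is the specific
#' growth rate in 1/h.
#'
#' @param counts A `time_course` of cell counts.
#' @param level Confidence level for the slope interval.
#' @return List with `mu`, `ci` (length 2), `se`, and the underlying `fit`.
#' @export
fit_growth_rate <- function(counts, level = 0.95) {
  if (any(counts$value <= 0)) stop("cell counts must be positive",
                                   call. = FALSE)
  if (nrow(counts) < 3L) stop("need at least 3 counts", call. = FALSE)
  fit <- stats::lm(log(value) ~ time, data = counts)
  mu <- unname(stats::coef(fit)["time"])
  ci <- tryCatch(unname(stats::confint(fit, "time", level = level)),
                 error = function(e) c(NA_real_, NA_real_))
  list(mu = mu, ci = as.numeric(ci),
       se = unname(summary(fit)$coefficients["time", "Std. Error"]),
       fit = fit)
}

#' First-order degradation rate from a cell-free time course
#'
#' Log-linear decay fit; `k = -slope`, clamped at zero (an increasing
#' cell-free series yields `k = 0` with a warning).
#'
#' @param cell_free A `time_course` measured without cells.
#' @return List with `k` (1/h) and the underlying `fit`.
#' @export
fit_degradation_rate <- function(cell_free) {
  if (nrow(cell_free) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(cell_free$value <= 0)) stop("cell-free values must be positive for ",
                                      "a log-linear fit", call. = FALSE)
  fit <- stats::lm(log(value) ~ time, data = cell_free)
  k <- -unname(stats::coef(fit)["time"])
  if (k < 0) {
    warning("cell-free series increases over time; degradation rate clamped ",
            "to 0")
    k <- 0
  }
  list(k = k, fit = fit)
}

#' Medium amount model A(t) under exponential growth and degradation
#'
#' Solves `dA/dt = q X0 exp(mu t) - k A` with `A(0) = A0`:
#' `A(t) = A0 exp(-kt) + q X0 (exp(mu t) - exp(-kt)) / (mu + k)`,
#' with the limiting forms at `mu + k = 0` and `mu = k = 0`.
#'
#' @param t Time (h). @param A0 Initial amount (nmol).
#' @param q Specific exchange rate (nmol/1e6 cells/h; secretion > 0,
#'   uptake < 0). @param X0 Initial cell number (1e6 cells).
#' @param mu Specific growth rate (1/h). @param k Degradation rate (1/h).
#' @return Amounts at `t`.
#' @export
amount_model <- function(t, A0, q, X0, mu, k = 0) {
  if (abs(mu + k) < 1e-12) {
    if (abs(k) < 1e-12) {
      A0 + q * X0 * t
    } else {
      A0 * exp(-k * t) + q * X0 * t * exp(-k * t)
    }
  } else {
    A0 * exp(-k * t) + q * X0 * (exp(mu * t) - exp(-k * t)) / (mu + k)
  }
}

#' Fit a specific uptake/secretion rate from a concentration time course
#'
#' Least-squares fit of [amount_model()] with `mu`, `X0`, `k` supplied;
#' `A0` and `q` are the fitted parameters (the model is linear in both).
#' The 95% confidence interval for `|q|` comes from a seeded parametric
#' bootstrap.
#'
#' @param conc A `time_course` of amounts (nmol).
#' @param mu Specific growth rate (1/h).
#' @param X0 Initial cell number (1e6 cells).
#' @param k First-order degradation rate (1/h; 0 unless degradable).
#' @param metabolite Label used in reports.
#' @param n_boot Bootstrap resamples (0 disables the CI).
#' @param seed RNG seed for the bootstrap.
#' @param level Confidence level.
#' @return An `exoflux_result`: `metabolite`, `direction` (uptake/secretion),
#'   `q` (signed), `flux` (=|q|), `ci` on |q|, `A0`, `n`.
#' @export
fit_exchange_rate <- function(conc, mu, X0, k = 0, metabolite = "metabolite",
                              n_boot = 1000L, seed = 1L, level = 0.95) {
  t <- conc$time
  y <- conc$value
  # Basis: A(t) = A0 * f1(t) + q * f2(t)
  f1 <- exp(-k * t)
  f2 <- if (abs(mu + k) < 1e-12) {
    if (abs(k) < 1e-12) X0 * t else X0 * t * exp(-k * t)
  } else {
    X0 * (exp(mu * t) - exp(-k * t)) / (mu + k)
  }
  fit <- stats::lm(y ~ 0 + f1 + f2)
  A0 <- unname(stats::coef(fit)[1])
  q <- unname(stats::coef(fit)[2])
  sigma <- summary(fit)$sigma
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    yhat <- stats::fitted(fit)
    qs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        yb <- yhat + stats::rnorm(length(yhat), sd = sigma)
        unname(stats::coef(stats::lm(yb ~ 0 + f1 + f2))[2])
      }, 0)
    })
    alpha <- (1 - level) / 2
    ci <- sort(abs(stats::quantile(qs, c(alpha, 1 - alpha), names = FALSE)))
  }
  structure(
    list(metabolite = metabolite,
         direction = if (q < 0) "uptake" else "secretion",
         q = q, flux = abs(q), ci = ci, A0 = A0, n = length(y),
         sigma = sigma),
    class = "exoflux_result"
  )
}

#' @export
print.exoflux_result <- function(x, ...) {
  cat(sprintf("%s %s flux %.1f nmol/1e6 cells/h (95%% CI %.1f, %.1f; n = %d)\n",
              x$metabolite, x$direction, x$flux, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Percent change between conditions
#'
#' `100 * (fhdim - parental) / parental`, rounded to integer for reporting:
#' positive means the flux increased in the FH-diminished condition.
#'
#' @param parental,fhdim Flux magnitudes in the two conditions.
#' @param digits Rounding for the reported value (integer per convention).
#' @return Signed percent change.
#' @export
percent_change <- function(parental, fhdim, digits = 0) {
  if (parental == 0) stop("percent change undefined for zero reference flux",
                          call. = FALSE)
  round(100 * (fhdim - parental) / parental, digits)
}

#' Flux ratio
#'
#' Ratio of two flux magnitudes (e.g. lactate secretion / glucose uptake),
#' rounded to two decimals for reporting.
#'
#' @param numerator,denominator Flux magnitudes.
#' @param digits Rounding digits.
#' @return The rounded ratio.
#' @export
flux_ratio <- function(numerator, denominator, digits = 2) {
  if (denominator <= 0) stop("flux ratio needs a positive denominator",
                             call. = FALSE)
  round(numerator / denominator, digits)
}
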