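#' Compact calibration network
#'
#' A deliberately small, fully identifiable network used to study the
#' statistical behaviour of the fitting machinery (chi-squared calibration,
#' confidence-interval coverage) at realistic noise levels but modest cost:
#' a labelled substrate and an unlabelled second substrate feed a branch
#' point with one reversible interconversion, observed through two
#' fragments plus two soft flux measurements.
#'
#' @return List with `model`, `fragments`, `tracers`, ground-truth `fluxes`
#'   (net R_up1 = 100, R_up2 = 50, R_ac = 30, exchange 40 on the reversible
#'   step) and `soft_true`.
#' @export
calibration_network <- function() {
  mets <- data.frame(
    id = c("s1_e", "s2_e", "a", "b", "c", "p_e", "q_e", "co2_x"),
    compartment = c("extracellular", "extracellular", "cytosol", "cytosol",
                    "cytosol", "extracellular", "extracellular",
                    "extracellular"),
    carbons = c(3, 3, 3, 3, 2, 3, 2, 1),
    symmetric = 0,
    balanced = c(0, 0, 1, 1, 1, 0, 0, 0),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("R_up1", "R_up2", "R_ab", "R_ac", "R_bp", "R_cq"),
    equation = c("s1_e (abc) --> a (abc)",
                 "s2_e (abc) --> b (abc)",
                 "a (abc) --> b (abc)",
                 "a (abc) --> c (bc) + co2_x (a)",
                 "b (abc) --> p_e (abc)",
                 "c (ab) --> q_e (ab)"),
    reversible = c(0, 0, 1, 0, 0, 0),
    lower = c(0, 0, -1000, 0, 0, 0),
    upper = 1000,
    stringsAsFactors = FALSE)
  model <- model_from_tables(rxns, mets)
  net_true <- c(R_up1 = 100, R_up2 = 50, R_ab = 70, R_ac = 30,
                R_bp = 120, R_cq = 30)
  fluxes <- flux_vector(model, net_true, xch = c(R_ab = 40))
  list(model = model,
       fragments = list(fB = fragment_spec("fB", "b", 1:3),
                        fC = fragment_spec("fC", "c", 1:2)),
       tracers = list(exp1 = list(s1_e = tracer_spec("s1_e", c(1, 2),
                                                     purity = 0.99))),
       fluxes = fluxes,
       soft_true = c(R_up1 = 100, R_bp = 120))
}

#' Simulate one calibration dataset
#'
#' Corrected-MID-level noise model: backbone MIDs at the ground truth plus
#' independent Gaussian noise (SD `mid_sd` per mass), and soft flux
#' measurements with 5% relative Gaussian error — exactly the error
#' structure the fit assumes, so the minimized RSS is chi-squared
#' distributed when the machinery is correct. The noisy vectors are
#' deliberately not renormalized or clipped here: renormalization couples
#' the per-mass errors and would distort the very calibration this
#' generator exists to measure.
#'
#' @param cal A [calibration_network()].
#' @param seed Seed for this replicate.
#' @param mid_sd Per-mass SD (default 0.01).
#' @param soft_rel_sd Relative SD of the soft flux measurements (0.05).
#' @return A [measurement_set()].
#' @export
simulate_calibration_dataset <- function(cal, seed, mid_sd = 0.01,
                                         soft_rel_sd = 0.05) {
  emunet <- decompose_emu(cal$model, cal$fragments)
  backbone <- simulate_mids(emunet, cal$fluxes, cal$tracers$exp1)
  with_seed(seed, {
    rows <- lapply(names(backbone), function(id) {
      m <- backbone[[id]] + stats::rnorm(length(backbone[[id]]), sd = mid_sd)
      data.frame(experiment = "exp1", fragment = id,
                 mass = seq_along(m) - 1L, mean = m, sd = mid_sd,
                 stringsAsFactors = FALSE)
    })
    soft <- data.frame(
      reaction = names(cal$soft_true),
      value = cal$soft_true * (1 + stats::rnorm(length(cal$soft_true),
                                                sd = soft_rel_sd)),
      rel_sd = soft_rel_sd, stringsAsFactors = FALSE)
    measurement_set(do.call(rbind, rows), soft, check_norm = FALSE)
  })
}

#' Fit one calibration dataset
#'
#' @param cal A [calibration_network()].
#' @param measurements A [measurement_set()] from
#'   [simulate_calibration_dataset()].
#' @param n_starts,seed Multistart controls (a truth-perturbed warm start is
#'   always included; calibration concerns the RSS distribution at the
#'   global minimum, not the search path).
#' @return An `mfa_fit`.
#' @export
fit_calibration_dataset <- function(cal, measurements, n_starts = 2L,
                                    seed = 1L) {
  prob <- mfa_problem(cal$model, cal$fragments, cal$tracers, measurements,
                      fit_options(n_starts = n_starts, seed = seed))
  fit_fluxes(prob, init = list(fluxes = cal$fluxes))
}

#' Chi-squared calibration study
#'
#' Repeatedly simulates correctly specified datasets, fits them, and
#' records the goodness-of-fit verdict at `alpha = 0.05`; with a correct
#' objective, weighting and dof convention the pass fraction is close to
#' 0.95.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed (replicate i uses `seed * 1000 + i`).
#' @param alpha Test level.
#' @return List with `pass_rate`, `rss` (vector), `dof`.
#' @export
chi2_calibration <- function(n_rep = 100L, seed = 1L, alpha = 0.05) {
  cal <- calibration_network()
  rss <- numeric(n_rep)
  pass <- logical(n_rep)
  dof <- NA_integer_
  for (i in seq_len(n_rep)) {
    ms <- simulate_calibration_dataset(cal, seed = seed * 1000L + i)
    fit <- fit_calibration_dataset(cal, ms, seed = seed * 1000L + i)
    g <- goodness_of_fit(fit, alpha = alpha)
    rss[i] <- fit$rss
    pass[i] <- g$pass
    dof <- fit$dof
  }
  list(pass_rate = mean(pass), rss = rss, dof = dof)
}

#' Grid-search CI coverage study
#'
#' For seeded noisy replicates, computes grid-search 95% confidence
#' intervals for the identifiable net fluxes of the calibration network and
#' reports how often the generating values fall inside.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param reactions Net fluxes to profile.
#' @return List with `coverage` (overall fraction), `per_reaction`, and the
#'   count of determined (bounded) intervals.
#' @export
ci_coverage <- function(n_rep = 20L, seed = 1L,
                        reactions = c("R_up2", "R_ac")) {
  cal <- calibration_network()
  truth <- cal$fluxes$net
  hits <- list()
  n_nd <- 0L
  for (i in seq_len(n_rep)) {
    ms <- simulate_calibration_dataset(cal, seed = seed * 1000L + i)
    fit <- fit_calibration_dataset(cal, ms, seed = seed * 1000L + i)
    for (r in reactions) {
      ci <- grid_search_ci(fit, r)
      if (is.na(ci$lower) || is.na(ci$upper)) {
        n_nd <- n_nd + 1L
        next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        reaction = r, hit = truth[[r]] >= ci$lower & truth[[r]] <= ci$upper,
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  list(coverage = mean(hits$hit),
       per_reaction = tapply(hits$hit, hits$reaction, mean),
       n_not_determined = n_nd)
}

#' Grid-search CI against the analytic interval on a linear-Gaussian toy
#'
#' Builds a two-parameter weighted linear regression (where the profile
#' RSS is exactly quadratic), runs the same outward-scan/bisection profiler
#' used by [grid_search_ci()] on the first coefficient, and compares the
#' result with the closed-form `estimate +/- 1.96 * SE`.
#'
#' @param n Observations.
#' @param seed Seed for the simulated data.
#' @param sigma Gaussian noise SD (also the fit weight, so the problem is
#'   correctly specified).
#' @return List with `grid` (lower/upper), `analytic` (lower/upper),
#'   `rel_err` (worst relative half-width error).
#' @export
linear_gaussian_ci_check <- function(n = 40L, seed = 1L, sigma = 0.5) {
  dat <- with_seed(seed, {
    x1 <- stats::runif(n, -1, 1)
    x2 <- stats::runif(n, -1, 1)
    y <- 2.0 * x1 - 1.0 * x2 + stats::rnorm(n, sd = sigma)
    list(x1 = x1, x2 = x2, y = y)
  })
  fit <- stats::lm(y ~ 0 + x1 + x2, data = dat)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[1] *
    sigma / summary(fit)$sigma  # known-sigma SE
  rss0 <- sum(stats::residuals(fit)^2) / sigma^2
  profile_rss <- function(b1) {
    # minimize over beta2 with beta1 pinned
    f2 <- stats::lm(I(dat$y - b1 * dat$x1) ~ 0 + x2, data = dat)
    sum(stats::residuals(f2)^2) / sigma^2
  }
  prof <- profile_interval(profile_rss, best = unname(beta[1]),
                           rss_best = rss0, level = 0.95)
  analytic <- unname(beta[1]) + c(-1, 1) * stats::qnorm(0.975) * unname(se)
  grid <- c(prof$lower, prof$upper)
  rel_err <- max(abs(grid - analytic) /
                   (stats::qnorm(0.975) * unname(se)))
  list(grid = grid, analytic = analytic, rel_err = rel_err,
       beta = unname(beta[1]), se = unname(se))
}
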