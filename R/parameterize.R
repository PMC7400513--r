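#' Parameterize the steady-state flux space
#'
#' Builds a coordinate parameterization of the affine solution set of
#' `S v = 0` (over balanced metabolites) together with any fixed-value
#' constraints. Free fluxes are chosen as actual reaction coordinates via
#' QR column pivoting, so recovering free values from an expanded flux
#' vector is exact (`v[free_ids]`).
#'
#' @param model A `network_model`.
#' @param fixed Named numeric vector of reactions pinned to fixed net flux
#'   values (hard measurements, biomass drain, ...).
#' @param prefer_free Optional character vector of reaction ids to prefer as
#'   free coordinates (e.g. measured uptakes); purely cosmetic for
#'   readability of the fit parameters.
#' @return A `flux_parameterization` with `free_ids`, `n_free`, and the
#'   internal solve structure used by [expand_fluxes()].
#' @export
parameterize_model <- function(model, fixed = numeric(0), prefer_free = NULL) {
  S <- stoichiometric_matrix(model)
  rxn_ids <- colnames(S)
  n <- length(rxn_ids)
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    bad <- setdiff(names(fixed), rxn_ids)
    if (length(bad)) stop("fixed constraint on unknown reaction(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    E <- matrix(0, nrow = length(fixed), ncol = n,
                dimnames = list(names(fixed), rxn_ids))
    for (r in names(fixed)) E[r, r] <- 1
    A <- rbind(A, E)
    b <- c(b, unname(fixed))
  }
  # Column order: put preferred-free (and non-fixed) columns last so pivoting
  # tends to leave them out of the dependent set.
  pref <- intersect(prefer_free %||% character(0), rxn_ids)
  ord <- c(setdiff(rxn_ids, pref), pref)
  qa <- qr(A[, ord, drop = FALSE])
  r <- qa$rank
  dep <- ord[qa$pivot[seq_len(r)]]
  free <- ord[qa$pivot[setdiff(seq_len(n), seq_len(r))]]
  free <- rxn_ids[rxn_ids %in% free]  # restore model order

  # Consistency of the constraints themselves (checked at a feasible point).
  if (r == n) {
    v <- qr.coef(qa, b)[order(qa$pivot)]
    names(v) <- ord
    resid <- max(abs(A %*% v[colnames(A)] - b))
    if (resid > 1e-6 * max(1, max(abs(b)))) {
      worst <- which.max(abs(A %*% v[colnames(A)] - b))
      stop("fixed constraints are inconsistent with steady state (worst ",
           "violated balance: ", rownames(A)[worst] %||% worst, ")",
           call. = FALSE)
    }
  }

  structure(
    list(model = model, S = S, A = A, b = b, fixed = fixed,
         free_ids = free, n_free = length(free), dep_ids = dep,
         rxn_ids = rxn_ids,
         qr_dep = qr(A[, dep, drop = FALSE])),
    class = "flux_parameterization"
  )
}

#' @export
print.flux_parameterization <- function(x, ...) {
  cat(sprintf("<flux_parameterization: %d reactions, %d fixed, %d free>\n",
              length(x$rxn_ids), length(x$fixed), x$n_free))
  if (x$n_free) cat("  free:", paste(x$free_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Expand free flux values into a full steady-state flux vector
#'
#' @param param A `flux_parameterization`.
#' @param free_values Numeric vector of free net-flux values (recycled by
#'   name when named; positional otherwise).
#' @param xch Named nonnegative exchange fluxes for reversible reactions
#'   (defaults to zero).
#' @param check_bounds If `TRUE` (default), bound violations throw; when
#'   `FALSE` they are recorded in the `violations` attribute so optimizers
#'   can penalize them.
#' @param tol Steady-state residual tolerance (relative to `max|v|`).
#' @return A `flux_vector` with elements `net` and `xch`.
#' @export
expand_fluxes <- function(param, free_values = numeric(0), xch = NULL,
                          check_bounds = TRUE, tol = 1e-9) {
  if (length(free_values) != param$n_free) {
    stop("expected ", param$n_free, " free values, got ", length(free_values),
         call. = FALSE)
  }
  if (!is.null(names(free_values)) && param$n_free) {
    free_values <- free_values[param$free_ids]
  }
  rhs <- param$b
  if (param$n_free) {
    rhs <- rhs - param$A[, param$free_ids, drop = FALSE] %*% free_values
  }
  v_dep <- qr.coef(param$qr_dep, rhs)
  v <- stats::setNames(numeric(length(param$rxn_ids)), param$rxn_ids)
  v[param$dep_ids] <- v_dep
  if (param$n_free) v[param$free_ids] <- free_values

  resid <- max(abs(param$S %*% v))
  if (resid > tol * max(1, max(abs(v)))) {
    stop("steady-state residual ", format(resid), " exceeds tolerance",
         call. = FALSE)
  }
  violations <- character(0)
  for (rx in param$model$reactions) {
    val <- v[rx$id]
    if (val < rx$lower - 1e-9 || val > rx$upper + 1e-9) {
      violations <- c(violations, sprintf(
        "%s = %.6g outside [%g, %g]", rx$id, val, rx$lower, rx$upper))
    }
  }
  if (length(violations) && check_bounds) {
    stop("flux bound violation: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  flux_vector(param$model, net = v, xch = xch, violations = violations)
}

#' Construct a flux vector
#'
#' @param model A `network_model`.
#' @param net Named net fluxes, one per reaction (nmol/1e6 cells/h).
#' @param xch Named nonnegative exchange fluxes for reversible reactions;
#'   missing entries default to 0.
#' @param violations Internal: bound-violation strings from [expand_fluxes()].
#' @return A `flux_vector`.
#' @export
flux_vector <- function(model, net, xch = NULL, violations = character(0)) {
  rxn_ids <- names(model$reactions)
  stopifnot(all(rxn_ids %in% names(net)))
  net <- net[rxn_ids]
  rev_ids <- reversible_reactions(model)
  x <- stats::setNames(numeric(length(rev_ids)), rev_ids)
  if (!is.null(xch) && length(xch)) {
    bad <- setdiff(names(xch), rev_ids)
    if (length(bad)) stop("exchange flux on irreversible reaction(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(xch < 0)) stop("exchange fluxes must be nonnegative", call. = FALSE)
    x[names(xch)] <- xch
  }
  structure(list(net = net, xch = x, violations = violations),
            class = "flux_vector")
}

# Directed forward/backward fluxes: fwd = net+ + xch, bwd = net- + xch.
directed_fluxes <- function(model, fluxes) {
  fwd <- pmax(fluxes$net, 0)
  bwd <- pmax(-fluxes$net, 0)
  for (r in names(fluxes$xch)) {
    fwd[r] <- fwd[r] + fluxes$xch[r]
    bwd[r] <- bwd[r] + fluxes$xch[r]
  }
  list(fwd = fwd, bwd = bwd)
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("<flux_vector: %d net fluxes, %d reversible>\n",
              length(x$net), length(x$xch)))
  invisible(x)
}
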