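#' Brute-force steady-state MIDs by full isotopomer balance
#'
#' Verification oracle for [simulate_mids()]: represents every metabolite by
#' its complete 2^n isotopomer distribution and iterates the steady-state
#' balance (each pool's distribution is the production-flux-weighted mixture
#' of the distributions its producing reactions deliver) to a fixed point.
#' Substrate pools are assumed independent when a reaction condenses two
#' molecules, exactly as the EMU method assumes. Intended for toy networks;
#' refuses state spaces above 2^20.
#'
#' @inheritParams simulate_mids
#' @param model A `network_model`.
#' @param fragments List of [fragment_spec()] objects to report.
#' @param tol Fixed-point convergence tolerance (max absolute change).
#' @param max_iter Iteration cap.
#' @return Named list of backbone-space MID vectors per fragment id.
#' @export
brute_force_mids <- function(model, fluxes, tracers = list(),
                             fragments, mix_fractions = list(),
                             abundance = default_abundance_table(),
                             tol = 1e-13, max_iter = 20000L) {
  nat13 <- natural_c13_fraction(abundance)
  events <- directed_events(model)
  produced <- produced_metabolites(events)
  mets <- model$metabolites
  carbons <- stats::setNames(mets$carbons, mets$id)

  n_states <- sum(2^carbons[produced])
  if (n_states > 2^20) {
    stop("isotopomer state space of ", n_states,
         " states exceeds the 2^20 oracle limit", call. = FALSE)
  }

  # Input distributions (metabolites never produced by a mapped reaction).
  dist <- list()
  input_mets <- setdiff(mets$id[carbons[mets$id] > 0], produced)
  for (m in input_mets) {
    tr <- tracers[[m]]
    dist[[m]] <- if (!is.null(tr)) {
      tracer_isotopomer_dist(tr, carbons[[m]], nat13)
    } else {
      natural_isotopomer_dist(carbons[[m]], nat13)
    }
  }
  for (m in produced) dist[[m]] <- natural_isotopomer_dist(carbons[[m]], nat13)

  fv <- directed_flux_values(model, fluxes)

  # Precompute, per event/target, the joint-substrate-state -> target-state
  # index map (joint index bit order follows concatenated source letters).
  plans <- list()
  for (e in events) {
    val <- e$weight * fv[[e$flux]]
    if (val <= 0) next
    src_mets <- vapply(e$sources, `[[`, "", "met")
    all_letters <- unlist(lapply(e$sources, `[[`, "letters"))
    for (tg in e$targets) {
      nt <- length(tg$letters)
      bitpos <- match(tg$letters, all_letters) - 1L  # joint bit of each target carbon
      n_joint <- 2^length(all_letters)
      joint_states <- 0:(n_joint - 1L)
      tgt_idx <- integer(n_joint)
      for (i in seq_len(nt)) {
        bit <- bitwAnd(bitwShiftR(joint_states, bitpos[i]), 1L)
        tgt_idx <- tgt_idx + bit * 2L^(i - 1L)
      }
      plans[[length(plans) + 1L]] <- list(
        target = tg$met, val = val, src_mets = src_mets, tgt_idx = tgt_idx + 1L,
        n_target_states = 2L^nt)
    }
  }

  inflow <- stats::setNames(numeric(length(produced)), produced)
  for (p in plans) inflow[p$target] <- inflow[p$target] + p$val
  starved <- names(inflow)[inflow <= 0]
  if (length(starved)) {
    stop("zero production flux for metabolite(s): ",
         paste(starved, collapse = ", "), call. = FALSE)
  }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in produced) {
      acc <- numeric(2^carbons[[m]])
      for (p in plans) {
        if (p$target != m) next
        joint <- 1
        for (sm in p$src_mets) joint <- as.vector(outer(joint, dist[[sm]]))
        # outer(joint, d): new bits are appended as high bits, matching the
        # concatenated-letter order used for tgt_idx.
        contrib <- numeric(p$n_target_states)
        tmp <- rowsum(joint * p$val, p$tgt_idx)
        contrib[as.integer(rownames(tmp))] <- tmp
        acc <- acc + contrib
      }
      new <- acc / inflow[[m]]
      delta <- max(delta, max(abs(new - dist[[m]])))
      dist[[m]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("brute-force isotopomer balance did not fully converge (delta = ",
            format(delta), ")")
  }

  # Marginalize to fragment MIDs.
  emu_mid <- function(met, pos) {
    d <- dist[[met]]
    if (is.null(d)) stop("no isotopomer distribution for ", met, call. = FALSE)
    states <- 0:(length(d) - 1L)
    k <- integer(length(d))
    for (p in pos) k <- k + bitwAnd(bitwShiftR(states, p - 1L), 1L)
    as.numeric(rowsum(d, k)[, 1])
  }
  out <- list()
  for (fr in fragments) {
    if (fr$metabolite %in% names(model$mixing_rules)) {
      contributors <- model$mixing_rules[[fr$metabolite]]
      fracs <- mix_fractions[[fr$metabolite]]
      if (is.null(fracs)) {
        fracs <- stats::setNames(rep(1 / length(contributors),
                                     length(contributors)), contributors)
      }
      mid <- 0
      for (m in contributors) mid <- mid + fracs[[m]] * emu_mid(m, fr$carbons)
    } else {
      mid <- emu_mid(fr$metabolite, fr$carbons)
    }
    out[[fr$id]] <- as.numeric(mid)
  }
  out
}
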