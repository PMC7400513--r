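# Directed label-production events shared by the EMU simulator and the
# brute-force isotopomer oracle. Each event carries: a directed flux name
# ("<rxn>.f" / "<rxn>.b"), an alternative-map weight, source instances
# (met + letter vector) and target instances (met + letter vector).
directed_events <- function(model) {
  events <- list()
  for (rx in model$reactions) {
    if (!rx$mapped) next
    for (map in rx$maps) {
      subs <- lapply(seq_along(rx$substrates), function(i) {
        list(met = rx$substrates[[i]]$met, letters = map$substrates[[i]])
      })
      prods <- lapply(seq_along(rx$products), function(i) {
        list(met = rx$products[[i]]$met, letters = map$products[[i]])
      })
      subs <- Filter(function(x) !is.null(x$letters), subs)
      prods <- Filter(function(x) !is.null(x$letters), prods)
      events[[length(events) + 1L]] <- list(
        flux = paste0(rx$id, ".f"), weight = map$weight,
        sources = subs, targets = prods)
      if (rx$reversible) {
        events[[length(events) + 1L]] <- list(
          flux = paste0(rx$id, ".b"), weight = map$weight,
          sources = prods, targets = subs)
      }
    }
  }
  events
}

# Metabolites with at least one mapped production event.
produced_metabolites <- function(events) {
  unique(unlist(lapply(events, function(e)
    vapply(e$targets, `[[`, "", "met"))))
}

emu_key <- function(met, pos) paste0(met, "[", paste(pos, collapse = ","), "]")

met_carbons <- function(model, met) {
  model$metabolites$carbons[model$metabolites$id == met]
}

met_balanced <- function(model, met) {
  model$metabolites$balanced[model$metabolites$id == met]
}

#' Decompose a model into the EMU network of observed fragments
#'
#' Traces each fragment's backbone elementary metabolite unit (EMU)
#' backwards through the atom maps, collecting the minimal set of EMUs whose
#' steady-state MIDs determine the fragment MIDs. Symmetric metabolites are
#' handled through their equal-weight alternative atom maps, and reversible
#' reactions contribute production events in both directions. Fragments on a
#' mixing pool expand to one target EMU per contributing compartment pool.
#'
#' @param model A validated `network_model`.
#' @param fragments A list of [fragment_spec()] objects.
#' @return An `emu_network` with size-stratified layers, ready for
#'   [simulate_mids()].
#' @export
decompose_emu <- function(model, fragments) {
  events <- directed_events(model)
  produced <- produced_metabolites(events)

  nodes <- new.env(parent = emptyenv())
  queue <- list()
  push <- function(met, pos) {
    key <- emu_key(met, pos)
    if (!is.null(nodes[[key]])) return(key)
    nc <- met_carbons(model, met)
    if (!length(nc)) stop("unknown metabolite ", met, call. = FALSE)
    if (any(pos > nc)) stop("EMU positions exceed carbons of ", met,
                            call. = FALSE)
    is_input <- !(met %in% produced)
    if (is_input && isTRUE(met_balanced(model, met))) {
      stop("unreachable EMU: ", key, " (balanced metabolite ", met,
           " has no mapped production)", call. = FALSE)
    }
    nodes[[key]] <- list(met = met, pos = pos, key = key,
                         size = length(pos), input = is_input,
                         events = list())
    if (!is_input) queue[[length(queue) + 1L]] <<- key
    key
  }

  # Seed with fragment backbone EMUs (mixing pools expand to contributors).
  for (fr in fragments) {
    mets <- if (fr$metabolite %in% names(model$mixing_rules)) {
      model$mixing_rules[[fr$metabolite]]
    } else fr$metabolite
    for (m in mets) push(m, fr$carbons)
  }

  while (length(queue)) {
    key <- queue[[1L]]; queue <- queue[-1L]
    node <- nodes[[key]]
    evs <- list()
    for (e in events) {
      for (tg in e$targets) {
        if (tg$met != node$met) next
        want <- tg$letters[node$pos]
        sources <- list()
        for (src in e$sources) {
          hit <- which(src$letters %in% want)
          if (length(hit)) {
            sources[[length(sources) + 1L]] <- list(met = src$met,
                                                    pos = sort(hit))
          }
        }
        found <- sum(vapply(sources, function(s) length(s$pos), 0L))
        if (found != length(want)) {
          stop("atom-map bookkeeping failure tracing ", key, " through ",
               e$flux, call. = FALSE)
        }
        src_keys <- vapply(sources, function(s) push(s$met, s$pos), "")
        src_sizes <- vapply(sources, function(s) length(s$pos), 0L)
        evs[[length(evs) + 1L]] <- list(flux = e$flux, weight = e$weight,
                                        sources = src_keys,
                                        sizes = src_sizes)
      }
    }
    if (!length(evs)) {
      stop("unreachable EMU: ", key, " (no production events)", call. = FALSE)
    }
    node$events <- evs
    nodes[[key]] <- node
  }

  all_nodes <- mget(ls(nodes), envir = nodes)
  sizes <- sort(unique(vapply(all_nodes, `[[`, 0L, "size")))
  layers <- lapply(sizes, function(s) {
    keys <- names(all_nodes)[vapply(all_nodes, function(n)
      n$size == s && !n$input, TRUE)]
    keys
  })
  names(layers) <- as.character(sizes)
  layers <- Filter(length, layers)

  net <- structure(
    list(model = model, fragments = fragments, nodes = all_nodes,
         layers = layers,
         n_nodes = length(all_nodes),
         input_keys = names(all_nodes)[vapply(all_nodes, `[[`, TRUE, "input")]),
    class = "emu_network"
  )
  net$plan <- compile_emu_plan(net)
  net
}

# Precompile the cascade into index-based structures so repeated solves
# (the inner loop of flux fitting) avoid name lookups: per layer a dense
# flux-to-A-matrix operator plus a list of convolution events.
compile_emu_plan <- function(net) {
  rxn_ids <- names(net$model$reactions)
  fv_names <- c(paste0(rxn_ids, ".f"), paste0(rxn_ids, ".b"))
  node_keys <- names(net$nodes)
  node_idx <- stats::setNames(seq_along(node_keys), node_keys)
  ndir <- length(fv_names)
  fidx_of <- stats::setNames(seq_len(ndir), fv_names)

  layers <- list()
  for (layer_name in names(net$layers)) {
    keys <- net$layers[[layer_name]]
    size <- as.integer(layer_name)
    n <- length(keys)
    pos_in_layer <- stats::setNames(seq_len(n), keys)
    Acoef <- matrix(0, n * n, ndir)  # maps directed fluxes -> vec(A)
    bevents <- list()
    for (i in seq_len(n)) {
      node <- net$nodes[[keys[i]]]
      for (e in node$events) {
        fi <- fidx_of[[e$flux]]
        # every event adds its flux to the diagonal (total inflow)
        Acoef[(i - 1L) * n + i, fi] <- Acoef[(i - 1L) * n + i, fi] + e$weight
        same_layer <- length(e$sources) == 1L && e$sizes[1L] == size &&
          !net$nodes[[e$sources[1L]]]$input
        if (same_layer) {
          j <- pos_in_layer[[e$sources[1L]]]
          Acoef[(j - 1L) * n + i, fi] <- Acoef[(j - 1L) * n + i, fi] - e$weight
        } else {
          bevents[[length(bevents) + 1L]] <- list(
            row = i, fidx = fi, w = e$weight,
            src = unname(node_idx[e$sources]))
        }
      }
    }
    layers[[layer_name]] <- list(size = size, n = n,
                                 rows = unname(node_idx[keys]),
                                 Acoef = Acoef, bevents = bevents,
                                 keys = keys)
  }
  list(fv_names = fv_names, node_idx = node_idx,
       input_rows = unname(node_idx[net$input_keys]), layers = layers)
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network: %d EMUs (%d inputs) in %d size layers for %d fragment(s)>\n",
              x$n_nodes, length(x$input_keys), length(x$layers),
              length(x$fragments)))
  invisible(x)
}

# Named directed flux vector ("<rxn>.f", "<rxn>.b") from a flux_vector.
directed_flux_values <- function(model, fluxes) {
  d <- directed_fluxes(model, fluxes)
  vals <- c(stats::setNames(d$fwd, paste0(names(d$fwd), ".f")),
            stats::setNames(d$bwd, paste0(names(d$bwd), ".b")))
  vals
}

#' Simulate steady-state fragment MIDs by the EMU cascade
#'
#' Solves the EMU balance layer by layer (dense LU per size) and assembles
#' backbone-space MIDs for every fragment of the network, applying mixing
#' fractions for fragments measured on mixing pools.
#'
#' @param emunet An `emu_network` from [decompose_emu()].
#' @param fluxes A `flux_vector` (steady state).
#' @param tracers Named list of [tracer_spec()] objects keyed by substrate
#'   id; input metabolites without a tracer get natural abundance.
#' @param mix_fractions Named list: mixing pool id -> named fractions over
#'   its contributors (must sum to 1). Pools absent from the list use equal
#'   fractions.
#' @param abundance Abundance table (for the natural 13C fraction).
#' @return Named list of backbone-space MID vectors, one per fragment id.
#' @export
simulate_mids <- function(emunet, fluxes, tracers = list(),
                          mix_fractions = list(),
                          abundance = default_abundance_table()) {
  nat13 <- natural_c13_fraction(abundance)
  model <- emunet$model
  fv <- directed_flux_values(model, fluxes)
  mids <- emu_solve(emunet, fv, tracers, nat13)
  assemble_fragment_mids(emunet, mids, mix_fractions)
}

# Core cascade solve; returns list indexed by plan node order.
emu_solve <- function(emunet, fv, tracers, nat13) {
  plan <- emunet$plan
  fvals <- unname(fv[plan$fv_names])
  mids <- vector("list", length(plan$node_idx))
  for (key in emunet$input_keys) {
    node <- emunet$nodes[[key]]
    tr <- tracers[[node$met]]
    mids[[plan$node_idx[[key]]]] <- if (!is.null(tr)) {
      tracer_emu_mid(tr, node$pos, nat13)
    } else {
      mid_convolve_all(rep(list(c(1 - nat13, nat13)), node$size))
    }
  }
  for (layer in plan$layers) {
    n <- layer$n
    A <- matrix(layer$Acoef %*% fvals, n, n)
    d <- diag(A)
    if (any(d <= 0)) {
      stop("singular EMU layer of size ", layer$size, ": ",
           paste(layer$keys[d <= 0], collapse = ", "),
           " has zero production flux", call. = FALSE)
    }
    B <- matrix(0, n, layer$size + 1L)
    for (e in layer$bevents) {
      val <- e$w * fvals[e$fidx]
      if (val == 0) next
      src <- mids[[e$src[1L]]]
      if (length(e$src) > 1L) {
        for (k in 2:length(e$src)) src <- mid_convolve(src, mids[[e$src[k]]])
      }
      B[e$row, ] <- B[e$row, ] + val * src
    }
    X <- tryCatch(solve(A, B), error = function(err) {
      stop("singular EMU layer of size ", layer$size, ": ",
           conditionMessage(err), call. = FALSE)
    })
    for (i in seq_len(n)) mids[[layer$rows[i]]] <- X[i, ]
  }
  stats::setNames(mids, names(plan$node_idx))
}

# Fragment MIDs from solved EMU MIDs, applying mixing-pool fractions.
assemble_fragment_mids <- function(emunet, mids, mix_fractions) {
  model <- emunet$model
  out <- list()
  for (fr in emunet$fragments) {
    if (fr$metabolite %in% names(model$mixing_rules)) {
      contributors <- model$mixing_rules[[fr$metabolite]]
      fracs <- mix_fractions[[fr$metabolite]]
      if (is.null(fracs)) {
        fracs <- stats::setNames(rep(1 / length(contributors),
                                     length(contributors)), contributors)
      }
      if (abs(sum(fracs) - 1) > 1e-9 || any(fracs < 0)) {
        stop("mixing fractions for ", fr$metabolite,
             " must be nonnegative and sum to 1", call. = FALSE)
      }
      mid <- 0
      for (m in contributors) {
        mid <- mid + fracs[[m]] * mids[[emu_key(m, fr$carbons)]]
      }
    } else {
      mid <- mids[[emu_key(fr$metabolite, fr$carbons)]]
    }
    assert_normalized(mid, paste0("simulated MID of ", fr$id))
    out[[fr$id]] <- as.numeric(mid)
  }
  out
}
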