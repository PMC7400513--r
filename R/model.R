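#' Load a compartmentalized atom-mapped network model
#'
#' The model dialect is tab-separated and human-diffable. The metabolite
#' table has columns `id`, `compartment` (cytosol / mitochondria /
#' extracellular / mixing), `carbons`, `symmetric` (0/1), `balanced` (0/1).
#' The reaction table has columns `id`, `equation`, `reversible` (0/1),
#' `lower`, `upper`. Equations use letter atom maps:
#'
#' ```
#' fum_m (abcd) --> mal_m (abcd)
#' hexp_c (abcdef) --> gap_c (cba) + gap_c (def)
#' ```
#'
#' Each letter names one carbon; every substrate-side letter must appear
#' exactly once on the product side (carbon conservation). Reactions without
#' atom maps (e.g. a lumped biomass drain) list `coefficient metabolite`
#' terms and take part in the stoichiometric balance only. Rotationally
#' symmetric metabolites (fumarate, succinate) are declared in the metabolite
#' table; every reaction touching them automatically receives equal-weight
#' (0.5/0.5) alternative atom maps with the symmetric molecule's carbon
#' string reversed, which implements the scrambling semantics.
#'
#' @param reactions Path to the reaction table.
#' @param metabolites Path to the metabolite table.
#' @param mixing Optional path to a mixing-rule table (columns `pool`,
#'   `contributors` with a comma-separated list); mixing pools combine
#'   compartment pools of one metabolite for measurements that cannot
#'   distinguish compartments, without carrying net flux.
#' @param dry_cell_weight Dry cell weight in pg/cell used to contextualize
#'   biomass coefficients (default 514).
#' @param biomass_id Reaction id of the lumped biomass drain, if present.
#' @return A `network_model` object.
#' @export
load_model <- function(reactions, metabolites, mixing = NULL,
                       dry_cell_weight = 514, biomass_id = "BIOMASS") {
  mets <- utils::read.delim(metabolites, stringsAsFactors = FALSE,
                            comment.char = "#")
  rxn_df <- utils::read.delim(reactions, stringsAsFactors = FALSE,
                              comment.char = "#")
  mixing_rules <- list()
  if (!is.null(mixing)) {
    mix_df <- utils::read.delim(mixing, stringsAsFactors = FALSE,
                                comment.char = "#")
    mixing_rules <- lapply(mix_df$contributors, function(s) {
      trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
    names(mixing_rules) <- mix_df$pool
  }
  model_from_tables(rxn_df, mets, mixing_rules,
                    dry_cell_weight = dry_cell_weight,
                    biomass_id = biomass_id)
}

#' Build a network model from in-memory tables
#'
#' Programmatic counterpart of [load_model()]: same columns, same
#' validation, no file round trip (used for toy and fixture networks).
#'
#' @param rxn_df Reaction data frame (`id`, `equation`, `reversible`,
#'   `lower`, `upper`).
#' @param mets Metabolite data frame (`id`, `compartment`, `carbons`,
#'   `symmetric`, `balanced`).
#' @param mixing_rules Named list: mixing pool -> contributor ids.
#' @inheritParams load_model
#' @return A `network_model`.
#' @export
model_from_tables <- function(rxn_df, mets, mixing_rules = list(),
                              dry_cell_weight = 514,
                              biomass_id = "BIOMASS") {
  need <- c("id", "compartment", "carbons", "symmetric", "balanced")
  if (!all(need %in% names(mets))) {
    stop("metabolite table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mets$symmetric <- as.logical(mets$symmetric)
  mets$balanced <- as.logical(mets$balanced)
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)

  need <- c("id", "equation", "reversible", "lower", "upper")
  if (!all(need %in% names(rxn_df))) {
    stop("reaction table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rxns <- lapply(seq_len(nrow(rxn_df)), function(i) {
    parse_reaction(rxn_df$id[i], rxn_df$equation[i],
                   as.logical(rxn_df$reversible[i]),
                   rxn_df$lower[i], rxn_df$upper[i], mets)
  })
  names(rxns) <- rxn_df$id

  model <- structure(
    list(metabolites = mets, reactions = rxns, mixing_rules = mixing_rules,
         biomass_id = if (biomass_id %in% names(rxns)) biomass_id else NULL,
         dry_cell_weight = dry_cell_weight),
    class = "network_model"
  )
  check_model_integrity(model)
  model
}

# Parse "a (abc) + 0.5 b --> c (ab) + co2 (c)" into instance lists.
parse_reaction <- function(id, equation, reversible, lower, upper, mets) {
  sides <- strsplit(equation, "-->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("reaction ", id, ": equation must contain '-->'", call. = FALSE)
  }
  parse_side <- function(side, role) {
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    lapply(terms, function(term) {
      map <- NULL
      m <- regmatches(term, regexec("^(.*)\\(([A-Za-z]+)\\)\\s*$", term))[[1]]
      if (length(m)) {
        term <- trimws(m[2])
        map <- strsplit(m[3], "")[[1]]
      }
      bits <- strsplit(term, "\\s+")[[1]]
      if (length(bits) == 2L) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        met <- bits[2]
        if (is.na(coef)) stop("reaction ", id, ": cannot parse term '", term,
                              "'", call. = FALSE)
      } else if (length(bits) == 1L) {
        coef <- 1
        met <- bits[1]
      } else {
        stop("reaction ", id, ": cannot parse term '", term, "'", call. = FALSE)
      }
      if (!met %in% mets$id) {
        stop("reaction ", id, ": metabolite '", met, "' is not declared",
             call. = FALSE)
      }
      nc <- mets$carbons[mets$id == met]
      if (!is.null(map) && length(map) != nc) {
        stop("reaction ", id, ": atom map for ", met, " has ", length(map),
             " carbons but the metabolite declares ", nc, call. = FALSE)
      }
      if (!is.null(map) && coef != 1) {
        stop("reaction ", id, ": atom-mapped instances must have ",
             "stoichiometric coefficient 1 (list instances separately)",
             call. = FALSE)
      }
      list(met = met, coef = coef, map = map)
    })
  }
  substrates <- parse_side(sides[1], "substrate")
  products <- parse_side(sides[2], "product")

  sub_letters <- unlist(lapply(substrates, `[[`, "map"))
  prod_letters <- unlist(lapply(products, `[[`, "map"))
  mapped <- !is.null(sub_letters) || !is.null(prod_letters)
  if (mapped) {
    if (anyDuplicated(sub_letters)) {
      stop("reaction ", id, ": duplicated substrate carbon letter", call. = FALSE)
    }
    if (anyDuplicated(prod_letters)) {
      stop("reaction ", id, ": duplicated product carbon letter", call. = FALSE)
    }
    if (!setequal(sub_letters %||% character(0), prod_letters %||% character(0))) {
      stop("carbon imbalance in reaction ", id, ": substrate carbons {",
           paste(sort(sub_letters), collapse = ""), "} vs product carbons {",
           paste(sort(prod_letters), collapse = ""), "}", call. = FALSE)
    }
  }
  if (!reversible && lower < 0) lower <- 0

  rx <- list(id = id, substrates = substrates, products = products,
             reversible = reversible, lower = lower, upper = upper,
             mapped = mapped)
  rx$maps <- build_symmetry_maps(rx, mets)
  rx
}

# Equal-weight alternative atom maps from symmetric metabolite instances.
# Each map is a list(substrates=, products=) of letter vectors per instance.
build_symmetry_maps <- function(rx, mets) {
  if (!rx$mapped) return(list())
  sym <- function(met) mets$symmetric[mets$id == met]
  variants <- function(instances) {
    alts <- lapply(instances, function(inst) {
      if (!is.null(inst$map) && isTRUE(sym(inst$met)) && length(inst$map) >= 2) {
        list(inst$map, rev(inst$map))
      } else {
        list(inst$map)
      }
    })
    # Cartesian product over instances.
    combos <- list(list())
    for (a in alts) {
      combos <- unlist(lapply(combos, function(cmb) {
        lapply(a, function(v) c(cmb, list(v)))
      }), recursive = FALSE)
    }
    combos
  }
  sub_v <- variants(rx$substrates)
  prod_v <- variants(rx$products)
  maps <- list()
  for (sv in sub_v) {
    for (pv in prod_v) {
      maps <- c(maps, list(list(substrates = sv, products = pv,
                                weight = 1 / (length(sub_v) * length(prod_v)))))
    }
  }
  maps
}

check_model_integrity <- function(model) {
  for (rx in model$reactions) {
    for (inst in c(rx$substrates, rx$products)) {
      if (!is.null(inst$map)) {
        nc <- model$metabolites$carbons[model$metabolites$id == inst$met]
        if (nc < 1) stop("metabolite ", inst$met, " appears in an atom map ",
                         "but declares 0 carbons", call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param model A `network_model`.
#' @return Matrix with one row per balanced metabolite, one column per
#'   reaction; entries are net stoichiometric coefficients.
#' @export
stoichiometric_matrix <- function(model) {
  bal <- model$metabolites$id[model$metabolites$balanced]
  S <- matrix(0, nrow = length(bal), ncol = length(model$reactions),
              dimnames = list(bal, names(model$reactions)))
  for (rx in model$reactions) {
    for (inst in rx$substrates) {
      if (inst$met %in% bal) S[inst$met, rx$id] <- S[inst$met, rx$id] - inst$coef
    }
    for (inst in rx$products) {
      if (inst$met %in% bal) S[inst$met, rx$id] <- S[inst$met, rx$id] + inst$coef
    }
  }
  S
}

#' Validate a network model
#'
#' Produces a report rather than throwing: per-reaction carbon balance,
#' dead-end balanced metabolites (produced but never consumed, or vice
#' versa), and mixing pools with fewer than two contributors.
#'
#' @param model A `network_model`.
#' @return A `validation_report` with a `findings` data frame (columns
#'   `type`, `subject`, `message`); zero rows means a clean model.
#' @export
validate_model <- function(model) {
  findings <- list()
  add <- function(type, subject, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  for (rx in model$reactions) {
    if (rx$mapped) {
      sl <- sort(unlist(lapply(rx$substrates, `[[`, "map")))
      pl <- sort(unlist(lapply(rx$products, `[[`, "map")))
      if (!identical(sl, pl)) {
        add("carbon_imbalance", rx$id, "mapped carbons differ between sides")
      }
    }
  }
  S <- stoichiometric_matrix(model)
  for (m in rownames(S)) {
    produced <- any(S[m, ] > 0)
    consumed <- any(S[m, ] < 0)
    if (produced && !consumed) add("dead_end", m, "produced but never consumed")
    if (consumed && !produced) add("dead_end", m, "consumed but never produced")
    if (!produced && !consumed) add("orphan", m, "balanced but unused")
  }
  for (pool in names(model$mixing_rules)) {
    contributors <- model$mixing_rules[[pool]]
    if (length(contributors) < 2L) {
      add("mixing_rule", pool, "mixing pool has fewer than two contributors")
    }
    missing <- setdiff(contributors, model$metabolites$id)
    if (length(missing)) {
      add("mixing_rule", pool,
          paste("unknown contributors:", paste(missing, collapse = ", ")))
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(type = character(0), subject = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(list(findings = findings, n_reactions = length(model$reactions),
                 n_metabolites = nrow(model$metabolites)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Model validation: %d reactions, %d metabolites, %d finding(s)\n",
              x$n_reactions, x$n_metabolites, nrow(x$findings)))
  if (nrow(x$findings)) print(x$findings)
  invisible(x)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model: %d reactions, %d metabolites (%d balanced), %d mixing pool(s)>\n",
              length(x$reactions), nrow(x$metabolites),
              sum(x$metabolites$balanced), length(x$mixing_rules)))
  invisible(x)
}

#' Reversible reactions of a model
#' @param model A `network_model`.
#' @return Character vector of reversible reaction ids.
#' @export
reversible_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, `[[`, TRUE, "reversible")]
}
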