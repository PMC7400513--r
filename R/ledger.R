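#' Read a cofactor stoichiometry table
#'
#' Tab-separated columns `reaction`, `cofactor`, `coefficient`: the net
#' production (positive) or consumption (negative) of each cofactor per
#' unit net flux. `NADH_m`/`NADH_c` distinguish mitochondrial and cytosolic
#' NADH; `ATP` rows are substrate-level phosphorylation with GTP counted as
#' ATP-equivalent.
#'
#' @param path File path; defaults to the table matching the reference
#'   model.
#' @param model Optional `network_model` for checking that every row refers
#'   to an existing reaction.
#' @return A `cofactor_stoichiometry` data frame.
#' @export
read_cofactor_table <- function(path = NULL, model = NULL) {
  if (is.null(path)) path <- pkg_extdata("reference_cofactors.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("reaction", "cofactor", "coefficient") %in% names(df)))
  if (!all(is.finite(df$coefficient))) {
    stop("non-finite cofactor coefficient", call. = FALSE)
  }
  if (!is.null(model)) {
    bad <- setdiff(df$reaction, names(model$reactions))
    if (length(bad)) stop("cofactor rows for unknown reaction(s): ",
                          paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("cofactor_stoichiometry", class(df))
  df
}

#' Cofactor production/consumption balance
#'
#' Per cofactor, sums the signed contributions `coefficient * net flux`
#' over all reactions; positive contributions count as production, negative
#' as consumption.
#'
#' @param fluxes A `flux_vector`.
#' @param stoich A `cofactor_stoichiometry` (from [read_cofactor_table()]).
#' @param strict Error if a flux-carrying reaction has no cofactor rows at
#'   all (guards against forgotten annotations); default `FALSE` because
#'   most transport reactions legitimately carry none.
#' @return A `cofactor_balance`: per-cofactor list with `production`,
#'   `consumption`, `net`, and the per-reaction `contributions`.
#' @export
cofactor_balance <- function(fluxes, stoich, strict = FALSE) {
  if (strict) {
    carrying <- names(fluxes$net)[abs(fluxes$net) > 1e-9]
    missing <- setdiff(carrying, unique(stoich$reaction))
    if (length(missing)) {
      stop("flux-carrying reaction(s) without cofactor rows: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out <- list()
  for (cf in unique(stoich$cofactor)) {
    rows <- stoich[stoich$cofactor == cf, , drop = FALSE]
    contrib <- stats::setNames(rows$coefficient * fluxes$net[rows$reaction],
                               rows$reaction)
    out[[cf]] <- list(
      production = sum(contrib[contrib > 0]),
      consumption = -sum(contrib[contrib < 0]),
      net = sum(contrib),
      contributions = contrib)
  }
  structure(out, class = "cofactor_balance")
}

#' ATP accounting configuration
#'
#' @param po_nadh ATP per NADH oxidized by oxidative phosphorylation
#'   (P/O ratio, default 2.3).
#' @param po_fadh2 ATP per FADH2 (default `2.3 * 1.5 / 2.5 = 1.38`,
#'   preserving the conventional NADH:FADH2 efficiency ratio; set to 2.3 to
#'   use a single P/O for both donors).
#' @param glycolysis Reaction ids whose substrate-level ATP terms form the
#'   glycolysis row.
#' @param tca Reaction ids whose substrate-level (GTP) ATP terms form the
#'   TCA row; all mitochondrial NADH and FADH2 OxPHOS ATP is attributed
#'   here.
#' @return An `atp_config` list.
#' @export
atp_config <- function(po_nadh = 2.3, po_fadh2 = 2.3 * 1.5 / 2.5,
                       glycolysis = c("HK", "PFK", "GAPD", "PK"),
                       tca = c("PDH", "CS", "IDH", "AKGDH", "SDH", "FH",
                               "MDH", "GDH")) {
  stopifnot(po_nadh > 0, po_fadh2 > 0)
  structure(list(po_nadh = po_nadh, po_fadh2 = po_fadh2,
                 glycolysis = glycolysis, tca = tca),
            class = "atp_config")
}

#' ATP production ledger with pathway attribution
#'
#' Attributes ATP production to glycolysis (net substrate-level
#' phosphorylation of the glycolytic reactions), the TCA cycle
#' (GTP-equivalents of TCA reactions plus OxPHOS ATP from net mitochondrial
#' NADH at the NADH P/O ratio and FADH2 at its P/O ratio), and "other"
#' production (OxPHOS ATP from net cytosolic NADH, shuttled at no cost, and
#' any remaining substrate-level production). Total consumption collects the
#' ATP-consuming reactions outside the glycolysis set (biomass synthesis,
#' carboxylation, ...). `total_net = glycolysis + tca + other - consumption`.
#'
#' @param fluxes A `flux_vector`.
#' @param stoich A `cofactor_stoichiometry`.
#' @param config An [atp_config()].
#' @return An `atp_ledger` with fields `glycolysis`, `tca`, `other`,
#'   `consumption`, `total_net` (nmol ATP/1e6 cells/h) and a `detail` list.
#' @export
atp_production <- function(fluxes, stoich, config = atp_config()) {
  bal <- cofactor_balance(fluxes, stoich)
  atp <- bal[["ATP"]]
  if (is.null(atp)) stop("stoichiometry has no ATP rows", call. = FALSE)
  contrib <- atp$contributions

  in_gly <- names(contrib) %in% config$glycolysis
  in_tca <- names(contrib) %in% config$tca
  glycolysis <- sum(contrib[in_gly])
  tca_slp <- sum(contrib[in_tca & contrib > 0])

  nadh_m <- if (!is.null(bal[["NADH_m"]])) bal[["NADH_m"]]$net else 0
  nadh_c <- if (!is.null(bal[["NADH_c"]])) bal[["NADH_c"]]$net else 0
  fadh2 <- if (!is.null(bal[["FADH2"]])) bal[["FADH2"]]$net else 0

  tca <- tca_slp + config$po_nadh * max(nadh_m, 0) +
    config$po_fadh2 * max(fadh2, 0)
  other_prod <- config$po_nadh * max(nadh_c, 0) +
    sum(contrib[!in_gly & !in_tca & contrib > 0])
  consumption <- -sum(contrib[!in_gly & !in_tca & contrib < 0])

  if (glycolysis < 0 || tca < 0) {
    stop("negative pathway ATP total; check the pathway reaction sets",
         call. = FALSE)
  }
  structure(
    list(glycolysis = glycolysis, tca = tca, other = other_prod,
         consumption = consumption,
         total_net = glycolysis + tca + other_prod - consumption,
         detail = list(balance = bal, tca_substrate_level = tca_slp,
                       nadh_m = nadh_m, nadh_c = nadh_c, fadh2 = fadh2,
                       config = config)),
    class = "atp_ledger"
  )
}

#' @export
print.atp_ledger <- function(x, ...) {
  cat(sprintf(paste0("ATP ledger (nmol/1e6 cells/h):\n",
                     "  glycolysis   %8.1f\n  TCA cycle    %8.1f\n",
                     "  other prod.  %8.1f\n  consumption  %8.1f\n",
                     "  total net    %8.1f\n"),
              x$glycolysis, x$tca, x$other, x$consumption, x$total_net))
  invisible(x)
}

#' Comparative ATP ledger report
#'
#' Side-by-side table of two conditions with the difference
#' (`parental - fhdim`, 1 decimal) and fold change (`fhdim / parental`,
#' 2 decimals); a zero reference entry leaves the fold change blank (NA).
#'
#' @param parental,fhdim `atp_ledger` objects, or named numeric vectors of
#'   pathway ATP fluxes (names become rows).
#' @return Data frame: `pathway`, `parental`, `fhdim`, `difference`,
#'   `fold_change`.
#' @export
ledger_report <- function(parental, fhdim) {
  as_rows <- function(x) {
    if (inherits(x, "atp_ledger")) {
      c(Glycolysis = x$glycolysis, `TCA cycle` = x$tca,
        `Total net` = x$total_net)
    } else unlist(x)
  }
  a <- as_rows(parental); b <- as_rows(fhdim)
  if (!identical(names(a), names(b))) {
    stop("pathway sets differ between conditions", call. = FALSE)
  }
  data.frame(
    pathway = names(a), parental = unname(a), fhdim = unname(b),
    difference = round(unname(a) - unname(b), 1),
    fold_change = ifelse(unname(a) == 0, NA_real_,
                         round(unname(b) / unname(a), 2)),
    stringsAsFactors = FALSE)
}
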