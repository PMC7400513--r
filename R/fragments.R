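#' Observed GC-MS fragments
#'
#' A fragment specification names the metabolite (or mixing pool) whose carbon
#' backbone a derivatized GC-MS ion reports on, which backbone carbon
#' positions the ion retains, and the elemental formula of the whole
#' derivatized ion (backbone carbons included). The formula drives natural
#' isotope abundance correction.
#'
#' @param id Fragment identifier.
#' @param metabolite Metabolite or mixing-pool id the backbone belongs to.
#' @param carbons Integer vector of retained backbone carbon positions
#'   (1-based), or a string such as `"1-4"` or `"1,2,5"`.
#' @param formula Elemental formula of the derivatized ion, e.g.
#'   `"C15H34NO3Si2"`. May be `NA` when only backbone-space simulation is
#'   needed.
#' @return An object of class `fragment_spec`.
#' @export
fragment_spec <- function(id, metabolite, carbons, formula = NA_character_) {
  if (is.character(carbons)) carbons <- parse_carbon_range(carbons)
  carbons <- sort(unique(as.integer(carbons)))
  if (length(carbons) < 1L || any(carbons < 1L)) {
    stop("fragment ", id, ": carbon positions must be positive integers",
         call. = FALSE)
  }
  counts <- parse_formula(formula)
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (length(counts) && n_c < length(carbons)) {
    stop("fragment ", id, ": formula ", formula, " has fewer carbons than ",
         "the tracked backbone", call. = FALSE)
  }
  structure(
    list(id = id, metabolite = metabolite, carbons = carbons,
         formula = formula, atoms = counts),
    class = "fragment_spec"
  )
}

parse_carbon_range <- function(s) {
  out <- integer(0)
  for (part in strsplit(s, ",", fixed = TRUE)[[1]]) {
    part <- trimws(part)
    if (grepl("-", part, fixed = TRUE)) {
      ab <- as.integer(strsplit(part, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      out <- c(out, as.integer(part))
    }
  }
  out
}

#' Read a fragment table
#'
#' Tab-separated columns: `id`, `metabolite`, `carbons` (range string),
#' `formula`.
#'
#' @param path File path; defaults to the reference fragment list shipped
#'   with the package.
#' @return A named list of [fragment_spec()] objects.
#' @export
read_fragment_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- pkg_extdata("reference_fragments.tsv")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  frags <- lapply(seq_len(nrow(df)), function(i) {
    fragment_spec(df$id[i], df$metabolite[i], df$carbons[i], df$formula[i])
  })
  names(frags) <- df$id
  frags
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment %s: %s C%s, ion %s>\n", x$id, x$metabolite,
              paste(x$carbons, collapse = ","),
              ifelse(is.na(x$formula), "(backbone only)", x$formula)))
  invisible(x)
}
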