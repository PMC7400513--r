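#' Natural isotope abundance tables
#'
#' An abundance table maps each element to the probabilities of the integer
#' mass shifts (+0, +1, +2, ...) of a single atom drawn at natural abundance.
#' The shipped defaults are the IUPAC representative isotopic compositions;
#' mass shifts with no stable isotope (e.g. +3 for sulfur) carry probability
#' zero.
#'
#' @param path Path to a tab-separated table with columns `element` and
#'   `probabilities` (comma-separated, one value per mass shift starting at
#'   +0). Defaults to the table shipped with the package.
#' @return A named list of numeric probability vectors, one per element.
#' @export
read_abundance_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- pkg_extdata("isotope_abundance.tsv")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("element", "probabilities") %in% names(df)))
  tab <- lapply(df$probabilities, function(s) {
    as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  names(tab) <- df$element
  for (el in names(tab)) {
    p <- tab[[el]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("abundance table entry for ", el, " is not a probability vector",
           call. = FALSE)
    }
    tab[[el]] <- p / sum(p)
  }
  tab
}

.abundance_cache <- new.env(parent = emptyenv())

#' @rdname read_abundance_table
#' @export
default_abundance_table <- function() {
  if (is.null(.abundance_cache$tab)) {
    .abundance_cache$tab <- read_abundance_table(NULL)
  }
  .abundance_cache$tab
}

#' Natural 13C fraction
#'
#' The +1 mass-shift probability of a single carbon at natural abundance,
#' used for every unlabelled carbon position of tracer substrates and
#' unlabelled model inputs.
#'
#' @param table An abundance table.
#' @return Scalar fraction (0.0107 for the shipped IUPAC table).
#' @export
natural_c13_fraction <- function(table = default_abundance_table()) {
  table[["C"]][2]
}

# Mass-shift distribution of `n` atoms of one element at natural abundance.
element_shift_distribution <- function(element, n, table) {
  if (n == 0) return(1)
  p <- table[[element]]
  if (is.null(p)) stop("element ", element, " missing from abundance table",
                       call. = FALSE)
  out <- 1
  for (i in seq_len(n)) out <- mid_convolve(out, p)
  out
}

# Parse an elemental formula such as "C10H21NO3Si" into named atom counts.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse elemental formula: ", formula, call. = FALSE)
  }
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts
}
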