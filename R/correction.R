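#' Natural isotope abundance correction matrices
#'
#' GC-MS measures the mass isotopomer distribution (MID) of a derivatized ion,
#' where silicon, sulfur, and every carbon outside the traced backbone
#' contribute natural-abundance mass shifts on top of the tracer-derived
#' backbone labelling. `build_correction_matrix()` constructs the linear map
#' from the backbone-space MID (length n+1 for n tracked carbons) to the raw
#' measured MID. Column j is the mass-shift distribution of the ion given
#' exactly j labelled backbone carbons, i.e. a shift of j convolved with the
#' natural-abundance distribution of all non-backbone atoms. Rows are
#' truncated at `n + 1 + tail` masses, so column sums are slightly below one.
#'
#' @param fragment A [fragment_spec()] with an elemental formula.
#' @param table Abundance table from [read_abundance_table()].
#' @param tail Number of raw masses retained beyond M+n (default 4, enough
#'   for Si/S isotope tails of TBDMS/TMS derivatives).
#' @return An object of class `correction_matrix` with elements `matrix`
#'   (rows = raw masses, columns = backbone masses), `fragment`, `kappa`
#'   (condition number).
#' @export
build_correction_matrix <- function(fragment,
                                    table = default_abundance_table(),
                                    tail = 4L) {
  n <- length(fragment$carbons)
  atoms <- fragment$atoms
  if (!length(atoms)) {
    stop("fragment ", fragment$id, " has no elemental formula; cannot build ",
         "a correction matrix", call. = FALSE)
  }
  n_c <- if ("C" %in% names(atoms)) atoms[["C"]] else 0L
  if (n_c < n) {
    stop("fragment ", fragment$id, ": formula has fewer carbons than the ",
         "tracked backbone", call. = FALSE)
  }
  # Mass-shift distribution of everything that is not a traced backbone carbon.
  dists <- list(element_shift_distribution("C", n_c - n, table))
  for (el in setdiff(names(atoms), "C")) {
    dists <- c(dists, list(element_shift_distribution(el, atoms[[el]], table)))
  }
  shift <- mid_convolve_all(dists)

  n_raw <- n + 1L + as.integer(tail)
  M <- matrix(0, nrow = n_raw, ncol = n + 1L)
  for (j in 0:n) {
    len <- min(length(shift), n_raw - j)
    M[(j + 1L):(j + len), j + 1L] <- shift[seq_len(len)]
  }
  structure(
    list(matrix = M, fragment = fragment, shift = shift,
         kappa = kappa(M, exact = TRUE)),
    class = "correction_matrix"
  )
}

#' Forward-convolve a backbone MID with natural abundance
#'
#' The forward model used by the synthetic-data generator: applies the
#' correction matrix and renormalizes over the retained raw masses.
#'
#' @param mid Normalized backbone-space MID (length n+1).
#' @param cm A `correction_matrix` (or a [fragment_spec()], in which case the
#'   matrix is built with defaults).
#' @return Normalized raw-space MID of length `nrow(cm$matrix)`.
#' @export
convolve_natural <- function(mid, cm) {
  if (inherits(cm, "fragment_spec")) cm <- build_correction_matrix(cm)
  assert_normalized(mid, "backbone MID")
  if (length(mid) != ncol(cm$matrix)) {
    stop("backbone MID length ", length(mid), " does not match fragment ",
         cm$fragment$id, " (expected ", ncol(cm$matrix), ")", call. = FALSE)
  }
  raw <- drop(cm$matrix %*% mid)
  raw / sum(raw)
}

#' Correct a raw measured MID for natural isotope abundance
#'
#' Solves `matrix %*% x = raw` by nonnegative least squares and renormalizes,
#' so noisy measurements that leave the probability simplex are projected
#' back rather than producing negative abundances. Raw vectors shorter than
#' the retained mass range are zero-padded; small negative noise entries are
#' clipped to zero (and flagged).
#'
#' @inheritParams convolve_natural
#' @param raw Raw measured MID (need not be normalized).
#' @return Normalized backbone-space MID of length n+1, with attributes
#'   `clipped` (TRUE if negative inputs were clipped) and `conditioning`
#'   (warning string when the matrix condition number exceeds 1e8).
#' @export
correct_mid <- function(raw, cm) {
  if (inherits(cm, "fragment_spec")) cm <- build_correction_matrix(cm)
  n_raw <- nrow(cm$matrix)
  clipped <- any(raw < 0)
  raw <- pmax(raw, 0)
  if (length(raw) < ncol(cm$matrix)) {
    stop("raw MID for fragment ", cm$fragment$id, " has fewer than n+1 masses",
         call. = FALSE)
  }
  if (length(raw) < n_raw) raw <- c(raw, numeric(n_raw - length(raw)))
  if (length(raw) > n_raw) raw <- raw[seq_len(n_raw)]
  x <- pracma::lsqnonneg(cm$matrix, raw)$x
  if (sum(x) <= 0) stop("natural-abundance correction collapsed to zero for ",
                        cm$fragment$id, call. = FALSE)
  x <- x / sum(x)
  attr(x, "clipped") <- clipped
  if (cm$kappa > 1e8) {
    attr(x, "conditioning") <- sprintf(
      "correction matrix for %s is ill-conditioned (kappa = %.3g)",
      cm$fragment$id, cm$kappa)
  }
  x
}
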