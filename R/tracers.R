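#' Tracer specification
#'
#' Describes the isotopic composition of a fed substrate. Purity is applied
#' positionally and independently: each labelled carbon is 13C with
#' probability `purity`, and every unlabelled carbon position carries the
#' natural 13C fraction. A tracer may be a mixture of species (e.g. a
#' labelled species plus unlabelled carrier); mixture fractions must sum
#' to 1.
#'
#' @param substrate Model id of the fed substrate (an input metabolite).
#' @param positions 1-based labelled carbon positions (e.g. `c(1, 2)` for
#'   \[1,2-13C\]glucose, `1:5` for \[U-13C\]glutamine).
#' @param purity Isotopic purity of each labelled position, in (0, 1].
#' @param fraction Mixture fraction of this species.
#' @return A `tracer_spec`.
#' @export
tracer_spec <- function(substrate, positions, purity = 1, fraction = 1) {
  stopifnot(purity > 0, purity <= 1)
  structure(
    list(substrate = substrate,
         species = list(list(positions = as.integer(positions),
                             purity = purity, fraction = fraction))),
    class = "tracer_spec"
  )
}

#' Combine tracer species for one substrate
#' @param ... `tracer_spec` objects for the same substrate.
#' @return A single `tracer_spec` whose mixture fractions must sum to 1.
#' @export
tracer_mixture <- function(...) {
  parts <- list(...)
  subs <- unique(vapply(parts, `[[`, "", "substrate"))
  if (length(subs) != 1L) stop("mixture species must share a substrate",
                               call. = FALSE)
  species <- unlist(lapply(parts, `[[`, "species"), recursive = FALSE)
  tot <- sum(vapply(species, `[[`, 0, "fraction"))
  if (abs(tot - 1) > 1e-9) stop("mixture fractions must sum to 1",
                                call. = FALSE)
  structure(list(substrate = subs, species = species), class = "tracer_spec")
}

# Per-carbon 13C probabilities of one tracer species over given positions.
species_position_probs <- function(species, positions, nat13) {
  ifelse(positions %in% species$positions, species$purity, nat13)
}

# MID of an EMU (carbon subset) of a tracer substrate.
tracer_emu_mid <- function(tracer, positions, nat13) {
  mid <- 0
  for (sp in tracer$species) {
    p <- species_position_probs(sp, positions, nat13)
    m <- mid_convolve_all(lapply(p, function(pi) c(1 - pi, pi)))
    mid <- mid + sp$fraction * m
  }
  mid
}

# Full isotopomer distribution of a tracer substrate (bit i-1 = carbon i).
tracer_isotopomer_dist <- function(tracer, n_carbons, nat13) {
  out <- numeric(2^n_carbons)
  for (sp in tracer$species) {
    p <- species_position_probs(sp, seq_len(n_carbons), nat13)
    d <- numeric(2^n_carbons)
    for (s in 0:(2^n_carbons - 1)) {
      bits <- bitwAnd(bitwShiftR(s, 0:(n_carbons - 1L)), 1L)
      d[s + 1] <- prod(ifelse(bits == 1L, p, 1 - p))
    }
    out <- out + sp$fraction * d
  }
  out
}

# Natural-abundance isotopomer distribution (independent carbons).
natural_isotopomer_dist <- function(n_carbons, nat13) {
  tracer_isotopomer_dist(tracer_spec("x", integer(0), purity = 1),
                         n_carbons, nat13)
}
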