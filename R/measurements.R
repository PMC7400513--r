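#' Measurement set for flux fitting
#'
#' Bundles what the weighted least-squares fit consumes: corrected MID
#' measurements from one or more parallel tracer experiments (SD fixed per
#' mass, 0.01 by convention), soft extracellular flux measurements fitted
#' with a relative SD (5% for glucose uptake and lactate secretion), and
#' hard flux constraints (the other measured extracellular fluxes, fixed).
#'
#' @param mids Data frame with columns `experiment`, `fragment`, `mass`
#'   (0-based), `mean`, `sd`. Each (experiment, fragment) MID must be
#'   normalized.
#' @param soft Data frame with columns `reaction`, `value`, `rel_sd`.
#' @param fixed Named numeric vector of hard flux constraints.
#' @param check_norm Verify that each MID sums to ~1 (disable for raw
#'   per-mass noise that was deliberately not renormalized).
#' @return A `measurement_set`.
#' @export
measurement_set <- function(mids, soft = NULL, fixed = numeric(0),
                            check_norm = TRUE) {
  need <- c("experiment", "fragment", "mass", "mean", "sd")
  if (!all(need %in% names(mids))) {
    stop("mids needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(mids$sd <= 0)) stop("MID SDs must be positive", call. = FALSE)
  if (check_norm) {
    for (key in unique(paste(mids$experiment, mids$fragment))) {
      sel <- paste(mids$experiment, mids$fragment) == key
      s <- sum(mids$mean[sel])
      if (abs(s - 1) > 1e-6) {
        stop("MID for ", key, " is not normalized (sum = ", format(s), ")",
             call. = FALSE)
      }
    }
  }
  if (!is.null(soft)) {
    stopifnot(all(c("reaction", "value", "rel_sd") %in% names(soft)))
  }
  structure(list(mids = mids, soft = soft, fixed = fixed),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set: %d MID masses (%d experiment(s)), %d soft, %d fixed>\n",
              nrow(x$mids), length(unique(x$mids$experiment)),
              if (is.null(x$soft)) 0L else nrow(x$soft), length(x$fixed)))
  invisible(x)
}

# Count fitted measurements. "independent" discounts one mass per MID vector
# (each normalized MID carries a sum-to-one constraint); "raw" counts every
# mass.
count_measurements <- function(measurements, count_mode = c("independent", "raw")) {
  count_mode <- match.arg(count_mode)
  mids <- measurements$mids
  groups <- unique(paste(mids$experiment, mids$fragment, sep = "\r"))
  n_mid <- if (count_mode == "raw") nrow(mids) else nrow(mids) - length(groups)
  n_soft <- if (is.null(measurements$soft)) 0L else nrow(measurements$soft)
  n_mid + n_soft
}
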