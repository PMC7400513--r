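#' Assess isotopic stationarity of MID time courses
#'
#' For each fragment, regresses every mass fraction on quench time and tests
#' the slope against zero; the fragment is called isotopically stationary
#' when no mass shows a significant drift after Bonferroni correction
#' across its masses.
#'
#' @param mid_series Data frame with columns `fragment`, `time`,
#'   `replicate`, `mass`, `value` (MID fractions per replicate and quench
#'   time).
#' @param alpha Test level before correction (default 0.05).
#' @return Data frame: `fragment`, `stationary` (TRUE/FALSE/NA for
#'   indeterminate), `min_adj_p`, `n_times`.
#' @export
assess_stationarity <- function(mid_series, alpha = 0.05) {
  need <- c("fragment", "time", "replicate", "mass", "value")
  if (!all(need %in% names(mid_series))) {
    stop("mid_series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(unique(mid_series$fragment), function(fr) {
    sub <- mid_series[mid_series$fragment == fr, , drop = FALSE]
    n_times <- length(unique(sub$time))
    if (n_times < 2L) {
      return(data.frame(fragment = fr, stationary = NA, min_adj_p = NA_real_,
                        n_times = n_times, stringsAsFactors = FALSE))
    }
    masses <- unique(sub$mass)
    pvals <- vapply(masses, function(m) {
      d <- sub[sub$mass == m, , drop = FALSE]
      if (stats::var(d$value) == 0) return(1)
      fit <- stats::lm(value ~ time, data = d)
      co <- summary(fit)$coefficients
      if (nrow(co) < 2L || !is.finite(co["time", "Pr(>|t|)"])) 1 else
        co["time", "Pr(>|t|)"]
    }, 0)
    adj <- pmin(pvals * length(masses), 1)  # Bonferroni
    data.frame(fragment = fr, stationary = all(adj >= alpha),
               min_adj_p = min(adj), n_times = n_times,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
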