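#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the caller's
# stream afterwards so seeded helpers never perturb the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Polynomial (mass-shift) convolution of two discrete distributions.
mid_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Convolve a list of distributions; identity is the point mass at shift 0.
mid_convolve_all <- function(xs) {
  out <- 1
  for (x in xs) out <- mid_convolve(out, x)
  out
}

assert_normalized <- function(x, what = "MID", tol = 1e-9) {
  if (any(x < -tol)) stop(what, " has negative entries", call. = FALSE)
  if (abs(sum(x) - 1) > tol) {
    stop(what, " does not sum to 1 (sum = ", format(sum(x)), ")", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locate a shipped data file (falls back to ./inst/extdata when the package
# is sourced rather than installed, e.g. during development).
pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mfa13c")
  if (nzchar(p)) return(p)
  local <- file.path("inst", "extdata", file)
  if (file.exists(local)) return(local)
  stop("cannot locate shipped data file ", file, call. = FALSE)
}
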