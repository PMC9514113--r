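#' Evaluate code with a temporary RNG seed
#'
#' All stochastic operations in the package funnel through this helper so that
#' a caller-supplied integer seed gives fully reproducible results without
#' disturbing the global RNG state.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive n reproducible sub-seeds (< 2^31) from one master seed.  Used to give
# patients, doses and ABC particles independent but reproducible RNG streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Trapezoidal cumulative integral of y over x (both numeric vectors).
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}
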