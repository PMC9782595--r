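#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm runif rpois mad median sd setNames
#' @importFrom utils read.csv write.csv read.table write.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' All stochastic stages draw their randomness from one master seed through
#' this splitting rule, so that an entire pipeline run is a pure function of
#' its configuration. The rule is a fixed integer hash of (seed, stream),
#' kept inside the 32-bit signed range.
#'
#' @param seed master seed (integer).
#' @param stream stream index (integer >= 0); distinct stages use distinct
#'   streams.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 69069 + as.double(stream) * 104729 + 12345) %% 2147483647
  as.integer(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) stopf("`%s` must be a single number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}
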