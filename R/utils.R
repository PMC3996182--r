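#' Round half away from zero
#'
#' Commercial rounding at `digits` decimals: ties go away from zero, so
#' `round_half_away(0.2665, 3)` is 0.267. Used wherever printed reference
#' proportions are matched, since they follow this convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against 0.49999... artefacts of binary floats
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 12347) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ventdss <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ventdss(sprintf("'%s' must be a single finite number", name))
}
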