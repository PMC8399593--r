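# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never perturbs the
#' caller's random stream. All stochastic operations in the package route
#' through this helper, which is what makes every stage a pure function of
#' (config, seed).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported metric tables use the
#' conventional half-up rule (0.74755 -> 0.7476).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector; `NA` values pass through.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop with a consistent message when a condition fails.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Validate an image-like numeric array/matrix of intensities in [0, 255].
check_intensities <- function(x, what = "image") {
  assert_that(is.numeric(x), sprintf("%s must be numeric", what))
  rng <- range(x)
  assert_that(rng[1] >= 0 && rng[2] <= 255,
              sprintf("%s intensities must lie in [0, 255]", what))
  invisible(TRUE)
}

# Clip numeric values into [lo, hi].
clip <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)
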