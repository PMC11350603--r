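#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Fold two integer seeds into one valid set.seed() argument.
combine_seeds <- function(a, b) {
  ((as.numeric(a) * 48271 + as.numeric(b)) %% 2147483647)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed percentages in counting
#' benchmarks conventionally round half up, which this helper implements.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_cfg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == floor(x)

check_div8 <- function(height, width) {
  if (height %% 8 != 0 || width %% 8 != 0)
    stop_cfg("image dimensions must be divisible by 8 (backbone stride), got ",
             height, "x", width)
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
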