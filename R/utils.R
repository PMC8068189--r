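#' @useDynLib qsrrisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor predict rnorm runif sd var coef
#' @importFrom utils combn read.csv read.delim write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is untouched afterwards.
with_seed <- function(seed, code) {
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
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic integer hash of an index set, mixed with a base seed.
# Arithmetic stays below 2^53 so it is exact in doubles.
hash_index_set <- function(idx, seed) {
  h <- sum((as.numeric(idx) * 2654435761) %% 1000000007)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

qstop <- function(...) stop(sprintf(...), call. = FALSE)

qlog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert column temperature to Kelvin
#'
#' All reciprocal-temperature arithmetic in the retention-surface model is
#' carried out in Kelvin; files carry degrees Celsius.
#'
#' @param temp_c temperature in degrees Celsius.
#' @return temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  if (any(temp_c <= -273.15)) qstop("temperature below absolute zero")
  temp_c + 273.15
}
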