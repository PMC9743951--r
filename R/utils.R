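#' @keywords internal
"_PACKAGE"

#' @useDynLib cfimpute, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif sd quantile
#' @importFrom utils read.csv write.csv
NULL

# Run `code` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no hidden global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept well below .Machine$integer.max.
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed)
  for (k in idx) s <- (s * 69069 + as.double(k)) %% 2147483563
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
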