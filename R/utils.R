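# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's random stream. A `NULL` seed evaluates the code as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# sample() without the scalar-x surprise: always samples from the vector.
safe_sample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Derive a reproducible child seed below 2^31 from a parent seed and index.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647L)
}
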