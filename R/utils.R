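# Internal helpers shared across modules.

#' Population standard deviation (denominator n)
#'
#' All dispersion and z-score computations in this package use the population
#' convention, i.e. `sqrt(mean((x - mean(x))^2))`.
#'
#' @param x numeric vector.
#' @return scalar standard deviation.
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Canonical unordered pair key "a|b" with a <= b lexicographically.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Derive a reproducible child seed from a master seed and a stream index.
# Keeps results independent of execution order across per-gene tasks.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + as.double(index) * 69621 + 1) %% 2147483647)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Stop with a consistent invalid-parameter error class.
stop_invalid <- function(...) {
  stop(structure(
    class = c("grn_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
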