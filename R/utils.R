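#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Truncate a ratio to a one-decimal percentage
#'
#' Reports `numerator/denominator` as a percentage truncated (floored, not
#' rounded) to one decimal place. This is the reporting convention used
#' throughout the package for printed percentages: 31/77 is reported as 40.2
#' and 2918/3016 as 96.7, both of which a round-half-up rule would print
#' differently.
#'
#' @param numerator non-negative count, at most `denominator`.
#' @param denominator positive count.
#' @return a numeric percentage with one decimal.
#' @examples
#' truncate_percent(31, 77)     # 40.2
#' truncate_percent(2918, 3016) # 96.7
#' @export
truncate_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("`denominator` must be > 0", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("`numerator` must be in [0, denominator]", call. = FALSE)
  }
  # small epsilon guards against 402.99999... artefacts of binary floats
  floor(numerator / denominator * 1000 + 1e-9) / 10
}
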