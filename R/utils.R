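# Internal helpers shared across modules.

utils::globalVariables(c("fitness_normZ", "drug_normZ", "highlight"))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator, runs
#' `expr`, and restores the previous state so package functions never disturb
#' the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a counter
#'
#' Counter-based splitting rule: repetition k always receives the same child
#' seed for a given master seed, independent of evaluation order. All
#' arithmetic stays exact in doubles and the result fits a 32-bit integer.
#'
#' @param seed master seed (integer below 2^31).
#' @param k counter (repetition index, >= 1).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k), k >= 0)
  # LCG-style mix; 2147483647 = 2^31 - 1 (prime)
  as.integer((abs(seed) %% 2147483647 * 69069 + k * 663608941) %% 2147483647)
}

# stop() with a classed condition so callers can distinguish error kinds
sk_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "screenkit_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
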