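# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded package functions never disturb
#' the global random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Row-wise softmax; guarded against overflow by subtracting the row max.
softmax_rows <- function(scores) {
  scores <- as.matrix(scores)
  shifted <- scores - apply(scores, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# Stop with a message naming the offending argument; used by validators.
fail_arg <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Deterministic integer sub-seed derived from a user seed and a stream index,
# kept below 2^31 so it is always a valid R integer.
sub_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1117) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent label ordering (radix = C collation) so fitted models
# and reports do not depend on LC_COLLATE.
sort_labels <- function(x) sort(x, method = "radix")
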