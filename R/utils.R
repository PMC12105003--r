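`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed for one operation
#'
#' Each stochastic operation draws from its own pseudo-random stream derived
#' from `(seed, operation name)`, so adding or reordering operations in a
#' workflow never perturbs the draws of the others.
#'
#' @param seed integer master seed.
#' @param op character scalar, operation name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
op_seed <- function(seed, op) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(op))
  u <- utf8ToInt(op)
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `code` under the stream for (seed, op), restoring the caller's RNG
# state afterwards so package functions never disturb user-level randomness.
with_stream <- function(seed, op, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(op_seed(seed, op))
  force(code)
}

# Draw n values in [lo, hi] pairwise separated by at least min_gap, optionally
# also separated from `avoid` values and outside `exclude` windows.
draw_spaced <- function(n, lo, hi, min_gap, avoid = numeric(0), exclude = NULL) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("draw_spaced: could not place ", n, " values in [",
                             lo, ", ", hi, "] with gap ", min_gap)
    x <- runif(1, lo, hi)
    if (length(exclude)) {
      inside <- vapply(exclude, function(w) x > w[1] && x < w[2], logical(1))
      if (any(inside)) next
    }
    if (all(abs(c(out, avoid) - x) >= min_gap)) out <- c(out, x)
  }
  out
}

stop_param <- function(...) stop(..., call. = FALSE)
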