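# Internal helpers shared across modules.

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (cohort, quality, connectomes, per-participant null ensembles, ...) use
#' child seeds derived deterministically from the root by a fixed
#' linear-congruential step keyed on a stream index, so that stages can be
#' re-run independently and two stages never share a stream.
#'
#' @param seed integer root seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  # LCG step modulo the Mersenne prime 2^31 - 1; keeps results exact in
  # double arithmetic (products stay below 2^53).
  m <- 2147483647
  x <- (abs(seed) %% m)
  for (k in seq_along(stream)) {
    x <- (x * 48271 + abs(stream[k]) %% m + 1) %% m
  }
  as.integer(x)
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# z-score a numeric vector (sample sd); errors on constant input
zscore <- function(x, what = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant variable '", what, "'", call. = FALSE)
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("'", what, "' must contain probabilities in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
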