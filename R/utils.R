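# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state
#' so that seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Centered moving average with shrinking windows at the edges. k is forced odd.
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Order-independent time average of a trace
#'
#' Mean of a numeric vector computed by summing its sorted values, so the
#' result is exactly invariant under any permutation of time points — in
#' particular under circular shifts. Used to verify the conservation property
#' of the shuffle null in floating point, where naive left-to-right summation
#' is order-sensitive in the last bit.
#'
#' @param x numeric vector.
#' @return scalar mean.
#' @export
trace_time_average <- function(x) {
  sum(sort(x)) / length(x)
}

# Validation error helper: all user-facing invariant violations name the field.
fail_validation <- function(field, msg) {
  stop(sprintf("validation error in '%s': %s", field, msg), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Frame-center times (seconds) for n samples at a given rate; t = 0 is the
# recording start and timestamps sit at sample centers.
sample_times <- function(n, rate_hz) {
  (seq_len(n) - 0.5) / rate_hz
}
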