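# Internal numeric / misc helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(a) {
  m <- apply(a, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(a[ok, , drop = FALSE] - m[ok])))
  out
}

#' Derive a per-stage child seed from a global seed
#'
#' A counter-based scheme so pipeline stages can be re-run independently while
#' remaining reproducible from one global seed. Result always fits in a 32-bit
#' integer.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.double(seed)) * 7919 + as.double(stage) * 104729) %% 2147483629)
}

assert_prob_vector <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("configuration error: `%s` must contain probabilities in [0, 1]", name),
         call. = FALSE)
  }
}

assert_sums_to_one <- function(p, name) {
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("configuration error: `%s` must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
}
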