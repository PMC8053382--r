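`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate a thunk under a fixed RNG seed without disturbing the caller's
## RNG stream; seed = NULL means "use the current stream".
with_seed_if <- function(seed, fun) {
  if (is.null(seed)) fun() else withr::with_seed(seed, fun())
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Stage-level seeds for the pipeline are drawn from a single master seed so
#' that one integer fully determines a run while stages stay independently
#' reproducible.
#'
#' @param seed master seed (single integer).
#' @param n number of sub-seeds.
#' @param labels optional names for the returned vector.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  out <- withr::with_seed(as.integer(seed),
                          sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(out) <- labels
  out
}

## All permutations of 1..n as an n! x n matrix (exhaustive permutation
## tests; guarded so nobody asks for n! rows by accident).
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  idx <- seq_len(n)
  do.call(rbind, lapply(idx, function(i) {
    rest <- idx[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

## All non-negative integer allocations of `total` over `parts` slots
## (compositions); used by the exhaustive d' range oracle.
integer_compositions <- function(total, parts) {
  stopifnot(total >= 0L, parts >= 1L)
  if (parts == 1L) return(matrix(as.integer(total), 1L, 1L))
  do.call(rbind, lapply(0:total, function(i) {
    cbind(as.integer(i), integer_compositions(total - i, parts - 1L))
  }))
}

## Monte-Carlo permutation p-value, (1 + b) / (1 + m) convention: the
## observed statistic is counted as part of the null set so p > 0 always.
mc_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}
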