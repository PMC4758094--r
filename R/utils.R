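# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

ssq <- function(x) sum(x^2)

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' Assign samples to cross-validation folds
#'
#' Round-robin fold assignment after a random shuffle, optionally stratified
#' so that each fold receives a balanced share of every stratum (e.g. class
#' label). Uses the current RNG state; call \code{set.seed()} beforehand for
#' reproducible folds.
#'
#' @param n number of samples.
#' @param k number of folds (2 \eqn{\le} k \eqn{\le} n).
#' @param strata optional length-\code{n} vector of stratum labels.
#' @return integer vector of fold indices in \code{1:k}.
#' @export
make_folds <- function(n, k, strata = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (k > n) stop(sprintf("more folds (%d) than samples (%d)", k, n))
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) stop("strata must have length n")
  fold <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- 1L + (offset + seq_along(idx) - 1L) %% k
    offset <- offset + length(idx)
  }
  if (length(unique(fold)) < k) stop("some folds are empty; reduce the fold count")
  fold
}

# angle in degrees between two vectors (test/diagnostic helper)
vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(ssq(a) * ssq(b))
  acos(pmin(1, pmax(-1, abs(ca)))) * 180 / pi
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(ssq(a) * ssq(b))
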