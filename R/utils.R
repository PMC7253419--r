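#' @include AllGenerics.R
NULL

#' Exact two-sided binomial p-values
#'
#' Vectorized exact test of observed successes \code{x} out of \code{n}
#' trials against null success probability \code{p0}.  The two-sided p-value
#' sums the probabilities of all outcomes no more likely than the observed
#' one (the classical minimum-likelihood rule, with the customary 1 + 1e-7
#' relative tolerance for ties), so results agree with
#' \code{stats::binom.test} to numerical precision.
#'
#' @param x integer vector of successes.
#' @param n integer vector of trials.
#' @param p0 null success probabilities (recycled).
#' @return numeric vector of p-values.
#' @export
binomExactP <- function(x, n, p0) {
  m <- max(length(x), length(n), length(p0))
  x <- rep_len(x, m); n <- rep_len(n, m); p0 <- rep_len(p0, m)
  vapply(seq_len(m), function(i) {
    d <- dbinom(0:n[i], n[i], p0[i])
    min(1, sum(d[d <= dbinom(x[i], n[i], p0[i]) * (1 + 1e-7)]))
  }, numeric(1))
}

#' Match estimated states to reference states
#'
#' Finds the state permutation minimizing the total absolute difference
#' between an estimated emission matrix and a reference one (exhaustive over
#' permutations; intended for small K).
#'
#' @param est,ref K x M emission matrices.
#' @return integer permutation \code{p} such that \code{est[p, ]} aligns with
#'   \code{ref}.
#' @export
matchStates <- function(est, ref) {
  K <- nrow(ref)
  stopifnot(nrow(est) == K, K <= 8L)
  perms <- .permutations(K)
  costs <- apply(perms, 1L, function(p) sum(abs(est[p, , drop = FALSE] - ref)))
  perms[which.min(costs), ]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Derive a named substream seed
#'
#' Each stochastic component of the simulator draws its randomness from a
#' substream seed derived from the master seed and the component name, so
#' that adding a component never perturbs the others.
#'
#' @param seed master seed (integer).
#' @param name component name.
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Median-of-ratios size factors
#'
#' The classical library-size normalization: each sample's factor is the
#' median across regions of its counts divided by the per-region geometric
#' mean, using only regions with all-positive counts.
#'
#' @param counts regions x samples matrix of non-negative counts.
#' @return numeric vector of size factors, one per sample.
#' @export
sizeFactors <- function(counts) {
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) return(rep(1, ncol(counts)))
  lg <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - geo)))
  unname(sf)
}

## row-normalize a matrix, masking empty rows as NA
.rowNormalize <- function(m) {
  rs <- rowSums(m, na.rm = TRUE)
  out <- m / rs
  out[rs == 0, ] <- NA_real_
  out
}

## constructor helpers used across modules
.BinnedTrack <- function(grid, values)
  new("BinnedTrack", grid = grid, values = as.numeric(values))

.BinMatrix <- function(grid, mat) {
  storage.mode(mat) <- "double"
  new("BinMatrix", grid = grid, mat = mat)
}

.Segmentation <- function(grid, states, K)
  new("Segmentation", grid = grid, states = as.integer(states),
      K = as.integer(K))
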