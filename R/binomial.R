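# Exact binomial upper-tail probability, the statistical core shared by the
# SNV detection model and the microsatellite-instability locus model. Both
# tests ask: given n trials with null success rate p, how surprising is it
# to observe at least k successes?
#
# The summation is done explicitly in log space (log binomial coefficients
# via lchoose, log-sum-exp) rather than through a normal approximation:
# locus read depths can be small and the decision thresholds (1e-3 for MSI
# loci, 1e-6 for SNV calls) sit deep in the tail where approximation error
# would flip classifications.

#' Exact binomial upper-tail probability P(X >= k)
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p)` by exact term-wise
#' summation of the probability mass function in log space.
#'
#' @param k Number of successes (non-negative integer, `k <= n`).
#' @param n Number of trials (non-negative integer).
#' @param p Null success probability in `[0, 1]`.
#' @return A probability in `[0, 1]`, monotone non-increasing in `k`.
#' @keywords internal
binom_upper_tail <- function(k, n, p) {
  k <- assert_count(k, "k")
  n <- assert_count(n, "n")
  assert_prob(p, "p")
  if (k > n) pp_stop("k (", k, ") must not exceed n (", n, ")")
  if (k <= 0L) return(1)
  if (p >= 1) return(1)
  if (p <= 0) return(0)
  ks <- seq.int(k, n)
  lg <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  m <- max(lg)
  min(1, exp(m) * sum(exp(lg - m)))
}
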