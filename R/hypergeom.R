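#' Log-space hypergeometric tail probabilities
#'
#' Computes `log10 P(X >= k)` (upper tail) or `log10 P(X <= k)` (lower tail)
#' for `X ~ Hypergeometric(N, K, n)`: `k` successes drawn in a sample of size
#' `n` from a population of `N` items of which `K` are successes. The whole
#' computation stays in log space, so p-values far below the smallest
#' representable double (e.g. 1e-268) yield finite scores.
#'
#' @param k Observed number of successes in the sample (vectorised).
#' @param K Number of successes in the population.
#' @param n Sample size.
#' @param N Population size.
#' @param tail `"upper"` for `P(X >= k)`, `"lower"` for `P(X <= k)`.
#'
#' @return `log10` of the tail probability; 0 when the tail probability is 1,
#'   `-Inf` only when the tail event is impossible (probability exactly 0).
#' @examples
#' log_hypergeom_tail(4, K = 4, n = 5, N = 10, tail = "upper")  # ~ -1.623
#' @seealso [hgt_score()]
#' @export
log_hypergeom_tail <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(K > N) || any(n > N)) abort("need K <= N and n <= N")
  if (any(k < 0) || any(k > pmin(n, K))) abort("need 0 <= k <= min(n, K)")
  if (tail == "upper") {
    lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  } else {
    lp <- phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  }
  # phyper can return values a hair above 0 in log space; clamp.
  pmin(lp, 0) / log(10)
}

#' Signed hypergeometric bias score (HGT score)
#'
#' The HGT score is `|log10(p)|` of a one-sided hypergeometric test, signed by
#' the direction of the bias: positive when the sample frequency `k/n` is at
#' least the population frequency `K/N` (over-representation, upper-tail
#' test), negative otherwise (under-representation, lower-tail test). A tail
#' probability of 1 gives a score of exactly 0. Ties (`k/n == K/N`) take the
#' upper tail and a positive sign.
#'
#' @inheritParams log_hypergeom_tail
#' @return Signed score, vectorised over the inputs.
#' @examples
#' hgt_score(4, K = 4, n = 5, N = 10)   # +1.623 (over-represented)
#' hgt_score(0, K = 5, n = 4, N = 10)   # -1.623 (under-represented)
#' @export
hgt_score <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(n == 0)) abort("n = 0 leaves the sample frequency undefined")
  over <- k / n >= K / N
  out <- numeric(m)
  if (any(over)) {
    out[over] <- -log_hypergeom_tail(k[over], K[over], n[over], N[over], "upper")
  }
  if (any(!over)) {
    out[!over] <- log_hypergeom_tail(k[!over], K[!over], n[!over], N[!over], "lower")
  }
  # -0 from a p = 1 lower tail is still 0
  out + 0
}
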