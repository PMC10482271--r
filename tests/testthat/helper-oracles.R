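# Independent oracles and fixture builders shared across the test files.
# The oracles never call the code paths they check: tails come from direct
# enumeration of the hypergeometric PMF, aspecificity from a naive loop.

# log(exp(a) + exp(b)) without leaving log space
logspace_add <- function(a, b) {
  if (is.infinite(a) && a < 0) return(b)
  if (is.infinite(b) && b < 0) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

# Exhaustive-enumeration oracle: log10 of the hypergeometric tail obtained by
# summing every PMF term of the support in log space (natural-log lchoose,
# accumulated with logspace_add).
oracle_log10_tail <- function(k, K, n, N, tail = "upper") {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  idx <- if (tail == "upper") seq(k, hi) else seq(lo, min(k, hi))
  if (tail == "upper" && k < lo) idx <- seq(lo, hi)
  if (tail == "lower" && k < lo) return(-Inf)
  lp <- lchoose(K, idx) + lchoose(N - K, n - idx) - lchoose(N, n)
  acc <- -Inf
  for (v in sort(lp)) acc <- logspace_add(acc, v)
  min(acc, 0) / log(10)
}

# Vectorised enumeration oracle for one (K, n, N): log10 upper and lower
# tails at every k in 0..min(n, K). Shifts by the global PMF maximum before
# the cumulative sums, which is exact to double precision for the small urns
# (N <= 60) it is used on.
oracle_tails_vec <- function(K, n, N) {
  ks <- 0:min(n, K)
  lo_s <- max(0, n - (N - K)); hi_s <- min(n, K)
  sup <- lo_s:hi_s
  lp <- lchoose(K, sup) + lchoose(N - K, n - sup) - lchoose(N, n)
  m <- max(lp)
  e <- exp(lp - m)
  low_sup <- log(cumsum(e)) + m                 # lower tail on the support
  upp_sup <- log(rev(cumsum(rev(e)))) + m       # upper tail on the support
  lower <- rep(-Inf, length(ks))
  upper <- rep(0, length(ks))                   # k below support: certain
  in_sup <- ks >= lo_s
  lower[in_sup] <- low_sup[ks[in_sup] - lo_s + 1]
  upper[in_sup] <- upp_sup[ks[in_sup] - lo_s + 1]
  list(k = ks, upper = pmin(upper, 0) / log(10),
       lower = pmin(lower, 0) / log(10))
}

oracle_hgt <- function(k, K, n, N) {
  if (k / n >= K / N) -oracle_log10_tail(k, K, n, N, "upper")
  else oracle_log10_tail(k, K, n, N, "lower")
}

# Naive sliding-window aspecificity (loop over every window start)
brute_aspecificity <- function(freqs, f2, fmean, window) {
  f2ref <- if (f2 > fmean) 0.9 * f2 else 1.1 * f2
  crossing <- if (f2 > fmean) freqs > f2ref else freqs <= f2ref
  w <- min(window, length(freqs))
  best <- -Inf
  for (s in seq_len(length(freqs) - w + 1)) {
    best <- max(best, mean(crossing[s:(s + w - 1)]))
  }
  100 * best
}

# Deterministic amino-acid encoding of an integer, for unique prefixes
aa_suffix <- function(i, width = 8) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  out <- character(width)
  for (p in seq_len(width)) {
    out[p] <- alpha[(i %% 20) + 1]
    i <- i %/% 20
  }
  paste(out, collapse = "")
}

toy_proteome <- function(pos2, prefix = "SYN") {
  n <- length(pos2)
  as_proteome(tibble::tibble(
    accession = sprintf("%s%05d", prefix, seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste0("M", pos2[i], aa_suffix(i))
    }, character(1))
  ))
}

# Hand-built three-term ontology (A superset, B nested high-fold, C disjoint)
# on a 240-protein proteome with known margins:
#   position-2 counts: S = 40, L = 40, G = 160
#   A = proteins 1..60   (S x30 at 1..30, G x30 at 31..60)
#   B = proteins 1..15 + 31..35  (S x15, G x5), fully inside A, fold 4.5 vs 3.0
#   C = proteins 61..100 (L x20 at 61..80, G x20 at 81..100), disjoint from A
abc_fixture <- function() {
  pos2 <- c(rep("S", 30), rep("G", 30),            # A
            rep("L", 20), rep("G", 20),            # C
            rep("S", 10), rep("L", 20), rep("G", 110))  # filler
  proteome <- toy_proteome(pos2)
  acc <- proteome$accession
  ann <- dplyr::bind_rows(
    tibble::tibble(term_id = "GO:A", accession = acc[1:60]),
    tibble::tibble(term_id = "GO:B", accession = acc[c(1:15, 31:35)]),
    tibble::tibble(term_id = "GO:C", accession = acc[61:100])
  ) |>
    dplyr::mutate(domain = "component", term_name = term_id)
  list(proteome = proteome, annotations = ann)
}

run_go_pipeline <- function(proteome, annotations, domain = "component",
                            config = nterm_config()) {
  build_go_contingency(annotations, proteome, domain = domain, config = config) |>
    screen_go_terms(config) |>
    filter_generic_terms(config) |>
    select_best_terms(config)
}
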