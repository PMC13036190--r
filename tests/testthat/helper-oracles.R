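# Independent oracles, written directly from the textbook definitions and
# kept free of any package internals.

# Benjamini-Hochberg step-up, brute force: adj_(i) = min_{j >= i} p_(j) n / j
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Exhaustive-enumeration upper-tail overlap probability: over all C(N, n)
# equally likely query draws from a universe of N genes of which the first K
# belong to the term, the fraction with >= k overlap.
enum_overlap_tail <- function(N, K, n, k) {
  cm <- utils::combn(N, n)
  ov <- colSums(cm <= K)
  mean(ov >= k)
}

# Textbook Pearson correlation from raw sums.
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
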