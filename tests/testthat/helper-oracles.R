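# Independent brute-force oracles used to check the statistical primitives.

# Two-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(m+n, m) group assignments of the pooled (tie-free) values.
mw_perm_pvalue <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(anyDuplicated(pooled) == 0)
  m <- length(x)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">"))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pooled), m)
  u_null <- apply(idx, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# Two-sided hypergeometric p-value by enumerating every draw of n items
# from an urn of N with K successes (feasible for N <= 12).
hyper_enum_pvalue <- function(k, K, n, N) {
  idx <- utils::combn(N, n)
  ks <- apply(idx, 2, function(d) sum(d <= K))
  min(1, 2 * min(mean(ks >= k), mean(ks <= k)))
}

# Step-up BH adjustment written out directly from its definition.
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(scaled))))
  adj[order(o)]
}
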