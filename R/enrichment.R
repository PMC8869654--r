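#' Two-sided hypergeometric p-value
#'
#' For an overlap of `k` query hits in a gene set of size `K`, a query of
#' size `n` and a background (universe) of size `N`, the two-sided p-value is
#' the doubled smaller tail of the hypergeometric(N, K, n) law, capped at 1:
#' `min(1, 2 * min(P(X >= k), P(X <= k)))`. A one-sided (enrichment-only)
#' variant is available.
#'
#' @param k Overlap count, `0 <= k <= min(K, n)`.
#' @param K Gene-set size within the background.
#' @param n Query size.
#' @param N Background size.
#' @param alternative `"two.sided"` (doubled smaller tail) or `"greater"`
#'   (enrichment tail only).
#' @return A p-value in \[0, 1\]. Deterministic.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 2/252: both tails at the extreme draw
#' @export
hypergeom_pvalue <- function(k, K, n, N,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ok <- length(k) == 1 && length(K) == 1 && length(n) == 1 && length(N) == 1 &&
    k >= 0 && K >= 0 && n >= 0 && K <= N && n <= N && k <= min(K, n) &&
    k >= max(0, K + n - N)
  if (!isTRUE(ok)) {
    abort(sprintf("inconsistent hypergeometric counts: k=%s K=%s n=%s N=%s",
                  k, K, n, N))
  }
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)  # P(X >= k)
  if (alternative == "greater") return(min(1, upper))
  lower <- phyper(k, K, N - K, n)                          # P(X <= k)
  min(1, 2 * min(upper, lower))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: p-values are ranked, scaled by m/rank, and a
#' cumulative minimum is taken from the largest rank down, so adjusted values
#' are monotone in the original ordering and each travels with its input
#' position.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a query list against a
#' background universe, with BH correction across the tested sets. Set
#' members are intersected with the background before testing (identifiers
#' the experiment never quantified cannot count for or against a set), and
#' sets with no background member are dropped. The natural background is the
#' set of proteins that passed the presence filter in the relevant
#' comparison -- the universe that was actually quantified.
#'
#' @param query Character vector of query identifiers (must be a subset of
#'   `background`).
#' @param background Character vector: the tested universe.
#' @param sets Gene-set tibble from [read_gene_sets()].
#' @param alpha Significance level on the adjusted p-value.
#' @param alternative Passed to [hypergeom_pvalue()].
#' @return A `lfq_enrichment` tibble: `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adjusted`, `significant`, `members_hit` (list-column),
#'   ordered by p-value.
#' @export
enrich <- function(query, background, sets, alpha = 0.05,
                   alternative = "two.sided") {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    abort("query must be a subset of the background universe")
  }
  N <- length(background)
  n <- length(query)
  rows <- purrr::pmap(list(sets$set_name, sets$members), function(nm, mem) {
    mem <- intersect(mem, background)
    K <- length(mem)
    if (K == 0) return(NULL)
    hit <- intersect(query, mem)
    tibble(
      set_name = nm, k = length(hit), K = K, n = n, N = N,
      p_value = hypergeom_pvalue(length(hit), K, n, N,
                                 alternative = alternative),
      members_hit = list(hit)
    )
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(set_name = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = double(),
                  p_adjusted = double(), significant = logical(),
                  members_hit = list())
  } else {
    out$p_adjusted <- bh_adjust(out$p_value)
    out$significant <- out$p_adjusted <= alpha
    out <- out[order(out$p_value, out$set_name),
               c("set_name", "k", "K", "n", "N", "p_value", "p_adjusted",
                 "significant", "members_hit")]
  }
  structure(out, class = c("lfq_enrichment", class(tibble())), alpha = alpha)
}
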