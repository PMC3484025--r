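# independent oracles, kept free of the package's sampling/annotation code

# Exact tail probability P(eQTL count >= observed) under uniform
# bin-respecting sampling without replacement, by brute-force enumeration
# of all per-bin subsets.  `is_eqtl` is a logical over universe rows,
# `bins` the per-row bin index, `need` the per-bin draw counts.
exact_matched_tail <- function(is_eqtl, bins, need, observed) {
  # per-bin distribution of the eQTL count among all k-subsets
  bin_ids <- sort(unique(bins))
  dists <- list()
  for (b in bin_ids) {
    k <- if (as.character(b) %in% names(need)) need[[as.character(b)]] else 0L
    idx <- which(bins == b)
    if (k == 0L) {
      dists[[length(dists) + 1L]] <- c(`0` = 1)
      next
    }
    combos <- utils::combn(idx, k)
    counts <- colSums(matrix(is_eqtl[combos], nrow = k))
    tab <- table(counts) / ncol(combos)
    dists[[length(dists) + 1L]] <- tab
  }
  # convolve the independent per-bin count distributions
  total <- c(`0` = 1)
  for (d in dists) {
    new <- numeric(0)
    for (i in seq_along(total)) {
      for (j in seq_along(d)) {
        s <- as.integer(names(total)[i]) + as.integer(names(d)[j])
        key <- as.character(s)
        new[key] <- (new[key] %||% 0) + total[[i]] * d[[j]]
      }
    }
    total <- new
  }
  sum(total[as.integer(names(total)) >= observed])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Two-sided Fisher P by direct enumeration of the hypergeometric support:
# the sum of P(k) over all k with P(k) <= P(observed), with the usual
# relative tolerance for ties.
hyper_two_sided <- function(n_a, n_b, n_int, universe) {
  support <- max(0, n_a + n_b - universe):min(n_a, n_b)
  probs <- stats::dhyper(support, n_a, universe - n_a, n_b)
  p_obs <- stats::dhyper(n_int, n_a, universe - n_a, n_b)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive sequential weighted sampling without replacement (one item at a
# time via sample(prob = )), the literal definition the fast
# exponential-keys implementation must match in distribution.
naive_weighted_draw <- function(n_items, k, w) {
  remaining <- seq_len(n_items)
  out <- integer(k)
  for (j in seq_len(k)) {
    pick <- sample(remaining, 1, prob = w[remaining])
    out[j] <- pick
    remaining <- setdiff(remaining, pick)
  }
  out
}

# exact binomial acceptance band: smallest/largest counts not rejected at
# two-sided level `alpha` for X ~ Binomial(n, p)
binom_band <- function(n, p, alpha = 0.01) {
  c(lo = stats::qbinom(alpha / 2, n, p),
    hi = stats::qbinom(1 - alpha / 2, n, p))
}
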