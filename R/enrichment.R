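#' Assign minor allele frequencies to bins
#'
#' MAF bins are left-closed, right-open intervals of width `bin_width`
#' ((0 to 5%], (5 to 10%], ... in the default configuration), except the
#' top bin, which is closed so that MAF = 0.5 is representable.  Bin
#' indices are zero-based: bin `b` covers `[b * w, (b + 1) * w)`.
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @param config an [enrichment_config()].
#' @return integer vector of zero-based bin indices.
#' @examples
#' assign_maf_bin(c(0.02, 0.05, 0.5))  # 0, 1, 9
#' @export
assign_maf_bin <- function(maf, config = enrichment_config()) {
  if (any(maf < 0 | maf > 0.5)) {
    validation_error("maf must lie in [0, 0.5]")
  }
  r <- maf / config$bin_width
  # guard binary-representation jitter at exact bin boundaries
  # (e.g. 0.15 / 0.05 evaluating just below 3)
  r <- ifelse(abs(r - round(r)) < 1e-9, round(r), r)
  pmin(as.integer(floor(r)), config$n_bins - 1L)
}

maf_bin_labels <- function(config) {
  lo <- (seq_len(config$n_bins) - 1L) * config$bin_width
  sprintf("[%.2f,%.2f%s", lo, lo + config$bin_width,
          c(rep(")", config$n_bins - 1L), "]"))
}

#' Tally a SNP list into MAF bins
#'
#' The per-bin tally of a hit list is the composition every randomized
#' null set must reproduce exactly.
#'
#' @param rsids character vector of SNP identifiers, all present in the
#'   universe.
#' @param universe a `snp_universe`.
#' @param config an [enrichment_config()].
#' @return an integer vector of length `n_bins` (class `bin_profile`),
#'   named by bin interval; sums to `length(rsids)`.
#' @export
bin_profile <- function(rsids, universe, config = enrichment_config()) {
  idx <- match(rsids, universe$rsid)
  if (anyNA(idx)) {
    validation_error(sprintf("rsid(s) not in universe: %s",
                             paste(rsids[is.na(idx)][1], collapse = ", ")))
  }
  bins <- assign_maf_bin(universe$maf[idx], config)
  counts <- tabulate(bins + 1L, nbins = config$n_bins)
  structure(stats::setNames(as.integer(counts), maf_bin_labels(config)),
            class = "bin_profile")
}

# indices of universe rows grouped by bin, and per-row bin ids
universe_bins <- function(universe, config) {
  bins <- assign_maf_bin(universe$maf, config)
  list(bins = bins,
       by_bin = split(seq_len(nrow(universe)), factor(bins, levels =
                        0:(config$n_bins - 1L))))
}

# core sampler: an n_snps x n_sets integer matrix of universe row indices;
# rows come in fixed bin blocks so bin matching is positional.  Sampling is
# uniform without replacement within each bin and set; consumes the RNG
# stream sequentially (callers fix the seed).
sample_null_index_matrix <- function(by_bin, profile, n_sets) {
  need <- as.integer(profile)
  avail <- lengths(by_bin)
  short <- which(need > avail)
  if (length(short)) {
    b <- short[1]
    validation_error(sprintf(
      "universe too small in MAF bin %s: need %d, have %d (deficit %d)",
      names(profile)[b] %||% b, need[b], avail[b], need[b] - avail[b]
    ))
  }
  n <- sum(need)
  m <- matrix(0L, nrow = n, ncol = n_sets)
  starts <- cumsum(c(1L, need))
  for (s in seq_len(n_sets)) {
    for (b in seq_along(need)) {
      k <- need[b]
      if (!k) next
      pool <- by_bin[[b]]
      m[starts[b]:(starts[b] + k - 1L), s] <-
        pool[sample.int(length(pool), k)]
    }
  }
  m
}

#' Draw MAF-matched randomized SNP sets
#'
#' Generates `n_sets` randomized SNP lists from the universe, each
#' reproducing the observed per-bin MAF composition exactly.  SNPs are
#' sampled uniformly without replacement *within* a set; the same SNP may
#' recur across sets, and the observed hit SNPs are not excluded from the
#' sampling frame.
#'
#' @param universe a `snp_universe`.
#' @param profile a [bin_profile()] of the observed hit list.
#' @param n_sets number of randomized sets.
#' @param seed integer seed; the whole draw is reproducible given it.
#' @param config an [enrichment_config()].
#' @return a list of `n_sets` character vectors of rsids.
#' @export
sample_matched_null <- function(universe, profile, n_sets, seed,
                                config = enrichment_config()) {
  ub <- universe_bins(universe, config)
  m <- with_seed(seed, sample_null_index_matrix(ub$by_bin, profile, n_sets))
  lapply(seq_len(ncol(m)), function(s) universe$rsid[m[, s]])
}

#' Empirical enrichment P-value from a null-count distribution
#'
#' The empirical P is the proportion of randomized sets whose eQTL count
#' matches or exceeds the observed count.  When no null set reaches the
#' observed count the stored proportion is exactly 0 and the display
#' string is `"<1/N"` (e.g. `"<0.001"` for N = 1000); no pseudo-count is
#' added.
#'
#' @param observed_count observed number of eQTL SNPs in the hit list.
#' @param null_counts integer vector of eQTL counts in the randomized sets.
#' @return list with `p` (proportion in [0, 1]) and `display` (string).
#' @examples
#' empirical_p(3, c(0, 1, 2, 3, 4))  # p = 0.4
#' @export
empirical_p <- function(observed_count, null_counts) {
  if (!length(null_counts) || any(null_counts < 0)) {
    validation_error("null_counts must be non-empty and non-negative")
  }
  n <- length(null_counts)
  k <- sum(null_counts >= observed_count)
  p <- k / n
  display <- if (k == 0L) {
    paste0("<", format(1 / n, scientific = FALSE, drop0trailing = TRUE))
  } else {
    format(p, scientific = FALSE, drop0trailing = TRUE)
  }
  list(p = p, display = display)
}

#' Run the eQTL enrichment test for one hit list in one tissue
#'
#' Counts the distinct hit SNPs that are significant eQTLs in the tissue,
#' draws `n_null_sets` MAF-matched randomized SNP sets from the universe,
#' scores each with the identical counting rule, and reports the empirical
#' enrichment P-value.  Exact bin matching of every null set is asserted
#' on every run.
#'
#' @param hits a `gwas_hits` object.
#' @param eqtl_records raw eQTL records (see [read_eqtl_table()]).
#' @param tissue tissue label to test.
#' @param universe a `snp_universe`.
#' @param config an [enrichment_config()]; supplies `n_null_sets` and
#'   `seed`.
#' @return an `enrichment_result`: list with `analysis_label`, `tissue`,
#'   `n_hits`, `observed_count`, `null_counts`, `empirical_p`, `p_display`,
#'   `n_null_sets`, `seed`.
#' @export
run_enrichment <- function(hits, eqtl_records, tissue, universe,
                           config = enrichment_config()) {
  analysis <- attr(hits, "analysis_label") %||% "unspecified"
  in_univ <- hits$rsid %in% universe$rsid
  if (any(!in_univ)) {
    warning(sprintf("%d hit(s) absent from the universe excluded",
                    sum(!in_univ)))
  }
  rsids <- unique(hits$rsid[in_univ])

  sig <- significant_eqtl_rsids(eqtl_records, universe, tissue, config)
  is_sig <- universe$rsid %in% sig
  observed <- sum(rsids %in% sig)

  ub <- universe_bins(universe, config)
  profile <- bin_profile(rsids, universe, config)
  m <- with_seed(config$seed,
                 sample_null_index_matrix(ub$by_bin, profile,
                                          config$n_null_sets))
  # bin-matching invariant: rows are bin blocks by construction; verify
  expected_bins <- rep(0:(config$n_bins - 1L), as.integer(profile))
  if (nrow(m) && !all(ub$bins[m] == expected_bins)) {
    stop("internal error: null set violates MAF bin matching")
  }
  null_counts <- if (nrow(m)) {
    as.integer(colSums(matrix(is_sig[m], nrow = nrow(m))))
  } else {
    integer(config$n_null_sets)
  }

  ep <- empirical_p(observed, null_counts)
  structure(list(analysis_label = analysis, tissue = tissue,
                 n_hits = length(rsids),
                 observed_count = as.integer(observed),
                 null_counts = null_counts,
                 empirical_p = ep$p, p_display = ep$display,
                 n_null_sets = as.integer(config$n_null_sets),
                 seed = as.integer(config$seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("eQTL enrichment: analysis '%s', tissue '%s'\n",
              x$analysis_label, x$tissue))
  cat(sprintf("  observed eQTL SNPs: %d of %d hits\n",
              x$observed_count, x$n_hits))
  cat(sprintf("  null mean %.2f (sd %.2f) over %d MAF-matched sets\n",
              mean(x$null_counts), stats::sd(x$null_counts),
              x$n_null_sets))
  cat(sprintf("  enrichment P = %s\n", x$p_display))
  invisible(x)
}
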