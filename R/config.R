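#' Analysis configuration for eQTL annotation and enrichment testing
#'
#' Bundles every tunable threshold of the pipeline.  The defaults are the
#' study conditions of the published analysis this package operationalizes:
#' 1,000 randomized null sets, minor-allele-frequency matching in 5% bins
#' over (0, 0.5], a 4 Mb cis window, a cis significance threshold of
#' P < 1e-4, a trans threshold of 0.05 / 25,834 (Bonferroni over expression
#' probes), and a GWAS inclusion threshold of P <= 1e-3.
#'
#' @param n_null_sets number of randomized MAF-matched SNP sets drawn for
#'   the empirical null distribution.
#' @param bin_width width of a minor-allele-frequency bin (frequency units).
#' @param n_bins number of MAF bins; `n_bins * bin_width` must cover
#'   (0, 0.5].
#' @param cis_window_bp maximum SNP-to-probe distance (bp, inclusive) for a
#'   same-chromosome association to be called cis.
#' @param cis_alpha significance threshold for cis eQTL (strict `<`).
#' @param trans_alpha_numerator numerator of the Bonferroni trans threshold;
#'   the threshold used is `trans_alpha_numerator / n_probes`.
#' @param n_probes number of expression probes the trans correction is
#'   taken over.
#' @param gwas_p_threshold GWAS P-value at or below which a SNP enters a
#'   hit list.
#' @param seed integer master seed for null-set sampling.
#'
#' @return an object of class `enrichment_config` (a validated list).
#' @examples
#' cfg <- enrichment_config(n_null_sets = 200, seed = 7)
#' cfg$cis_window_bp
#' @export
enrichment_config <- function(n_null_sets = 1000,
                              bin_width = 0.05,
                              n_bins = 10,
                              cis_window_bp = 4e6,
                              cis_alpha = 1e-4,
                              trans_alpha_numerator = 0.05,
                              n_probes = 25834,
                              gwas_p_threshold = 1e-3,
                              seed = 1L) {
  cfg <- list(
    n_null_sets = as.integer(n_null_sets),
    bin_width = bin_width,
    n_bins = as.integer(n_bins),
    cis_window_bp = cis_window_bp,
    cis_alpha = cis_alpha,
    trans_alpha_numerator = trans_alpha_numerator,
    n_probes = as.integer(n_probes),
    gwas_p_threshold = gwas_p_threshold,
    seed = as.integer(seed)
  )
  if (cfg$n_null_sets < 1) config_error("n_null_sets must be positive")
  if (cfg$n_bins < 1 || cfg$bin_width <= 0) {
    config_error("n_bins and bin_width must be positive")
  }
  if (cfg$n_bins * cfg$bin_width < 0.5 - 1e-12) {
    config_error("n_bins * bin_width must cover the MAF range (0, 0.5]")
  }
  for (f in c("cis_alpha", "trans_alpha_numerator", "gwas_p_threshold")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      config_error(sprintf("%s must lie in (0, 1)", f))
    }
  }
  if (cfg$cis_window_bp < 0) config_error("cis_window_bp must be >= 0")
  if (cfg$n_probes < 1) config_error("n_probes must be positive")
  structure(cfg, class = "enrichment_config")
}

#' @export
print.enrichment_config <- function(x, ...) {
  cat("eQTL enrichment configuration\n")
  cat(sprintf("  null sets: %d (seed %d)\n", x$n_null_sets, x$seed))
  cat(sprintf("  MAF bins: %d x %.3f\n", x$n_bins, x$bin_width))
  cat(sprintf("  cis window: %s bp, cis alpha < %g\n",
              format(x$cis_window_bp, big.mark = ","), x$cis_alpha))
  cat(sprintf("  trans alpha < %g / %d = %g\n", x$trans_alpha_numerator,
              x$n_probes, x$trans_alpha_numerator / x$n_probes))
  cat(sprintf("  GWAS inclusion: P <= %g\n", x$gwas_p_threshold))
  invisible(x)
}

# effective trans threshold
trans_alpha <- function(config) config$trans_alpha_numerator / config$n_probes
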