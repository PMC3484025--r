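#' Configuration for the synthetic study generator
#'
#' Describes a synthetic genotyping platform, per-tissue binary eQTL
#' structure, and GWAS hit lists with an optional planted enrichment.
#' Defaults mirror the structure of the real analysis at a desk-friendly
#' platform size: a 50,000-SNP universe, 500-SNP hit lists, three tissues
#' (two brain, one LCL), a 5% eQTL base rate, the published 16%
#' multi-gene-eQTL share and 58% cis share, and no planted enrichment
#' (`enrichment_multiplier = 1`, the null).
#'
#' @param n_universe number of SNPs on the synthetic platform.
#' @param maf_model MAF distribution: `list(dist = "uniform", min, max)`
#'   or `list(dist = "beta", shape1, shape2)` (a Beta rescaled to
#'   (0, 0.5]).
#' @param tissues character vector of tissue labels.
#' @param analyses character vector of primary-analysis labels.
#' @param eqtl_base_rate probability a SNP is a significant eQTL in a
#'   tissue; a scalar, or a vector of length `n_bins` for MAF-dependent
#'   rates.
#' @param multi_gene_rate probability an eQTL SNP targets two genes
#'   rather than one.
#' @param cis_fraction probability a simulated eQTL association is cis.
#' @param decoy_rate probability a non-eQTL SNP receives a non-significant
#'   decoy association row (exercises the significance thresholds).
#' @param n_hits hit-list size per analysis.
#' @param enrichment_multiplier odds multiplier (theta >= 1) with which
#'   eQTL SNPs enter a hit list; 1 plants no enrichment.
#' @param enrich_tissue tissue whose eQTL status drives the planted
#'   enrichment; defaults to the first tissue.
#' @param seed master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_universe = 50000,
                       maf_model = list(dist = "uniform",
                                        min = 0.01, max = 0.5),
                       tissues = c("parietal", "cerebellum", "lcl"),
                       analyses = c("SpecAll", "StrictAll",
                                    "SpecWestEur", "StrictWestEur"),
                       eqtl_base_rate = 0.05,
                       multi_gene_rate = 0.16,
                       cis_fraction = 0.58,
                       decoy_rate = 0.1,
                       n_hits = 500,
                       enrichment_multiplier = 1,
                       enrich_tissue = tissues[1],
                       seed = 1L) {
  cfg <- list(n_universe = as.integer(n_universe), maf_model = maf_model,
              tissues = tissues, analyses = analyses,
              eqtl_base_rate = eqtl_base_rate,
              multi_gene_rate = multi_gene_rate,
              cis_fraction = cis_fraction, decoy_rate = decoy_rate,
              n_hits = as.integer(n_hits),
              enrichment_multiplier = enrichment_multiplier,
              enrich_tissue = enrich_tissue, seed = as.integer(seed))
  if (cfg$n_universe < 1) config_error("n_universe must be >= 1")
  if (cfg$n_hits > cfg$n_universe) {
    config_error("n_hits cannot exceed n_universe")
  }
  probs <- c(cfg$eqtl_base_rate, cfg$multi_gene_rate, cfg$cis_fraction,
             cfg$decoy_rate)
  if (any(probs < 0 | probs > 1)) {
    config_error("rates and fractions must lie in [0, 1]")
  }
  if (cfg$enrichment_multiplier < 0) {
    config_error("enrichment_multiplier must be >= 0")
  }
  if (!cfg$maf_model$dist %in% c("uniform", "beta")) {
    config_error(sprintf("unknown maf_model dist '%s'", cfg$maf_model$dist))
  }
  structure(cfg, class = "sim_config")
}

# synthetic genome: 22 autosomes of 250 Mb, enough to exercise the 4 Mb
# cis window and cross-chromosome trans cases
.sim_chrom_len <- 250e6
.sim_n_chrom <- 22L

draw_maf <- function(n, model) {
  switch(model$dist,
         uniform = stats::runif(n, model$min, model$max),
         beta = 0.5 * stats::rbeta(n, model$shape1, model$shape2))
}

#' Simulate a SNP universe
#'
#' @param cfg a [sim_config()].
#' @param seed seed override; defaults to `cfg$seed`.
#' @return a `snp_universe` with rsids `sim_rs000001`, ... and positions
#'   uniform over 22 synthetic 250 Mb autosomes.
#' @export
simulate_universe <- function(cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    n <- cfg$n_universe
    df <- data.frame(
      rsid = sprintf("sim_rs%06d", seq_len(n)),
      chrom = as.character(sample.int(.sim_n_chrom, n, replace = TRUE)),
      pos = sample.int(.sim_chrom_len, n, replace = TRUE),
      maf = pmin(pmax(draw_maf(n, cfg$maf_model), 0), 0.5),
      stringsAsFactors = FALSE
    )
    new_snp_universe(df, "synthetic")
  })
}

#' Simulate per-tissue eQTL association tables
#'
#' Each SNP is independently flagged as a significant eQTL in each tissue
#' with its MAF bin's base rate.  Flagged SNPs receive one (or, with
#' probability `multi_gene_rate`, two) association rows whose probe
#' position is consistent with a drawn cis/trans class — cis probes land
#' within the 4 Mb window on the SNP's chromosome, trans probes on a
#' different chromosome — and whose P-value falls below the
#' class-appropriate threshold (log-uniform between 1e-12 and the
#' threshold).  Unflagged SNPs may receive decoy rows with P-values
#' log-uniform between the threshold and 1, so the binary statistic is
#' exercised on both sides of each cutoff.  Target gene labels are 1 Mb
#' genome tiles, so nearby probes naturally share genes across SNPs and
#' tissues.
#'
#' @param universe a `snp_universe`.
#' @param cfg a [sim_config()].
#' @param config an [enrichment_config()] supplying the thresholds.
#' @param seed seed override; defaults to `cfg$seed + 1`.
#' @return named list (one per tissue) of raw eQTL record data.frames.
#' @export
simulate_eqtl_map <- function(universe, cfg = sim_config(),
                              config = enrichment_config(),
                              seed = cfg$seed + 1L) {
  bins <- assign_maf_bin(universe$maf, config)
  rate <- if (length(cfg$eqtl_base_rate) == 1L) {
    rep(cfg$eqtl_base_rate, nrow(universe))
  } else {
    if (length(cfg$eqtl_base_rate) != config$n_bins) {
      config_error("per-bin eqtl_base_rate must have n_bins entries")
    }
    cfg$eqtl_base_rate[bins + 1L]
  }
  t_alpha <- trans_alpha(config)
  with_seed(seed, {
    out <- lapply(cfg$tissues, function(tissue) {
      flagged <- stats::runif(nrow(universe)) < rate
      idx <- which(flagged)
      n_rows <- 1L + (stats::runif(length(idx)) < cfg$multi_gene_rate)
      snp <- rep(idx, n_rows)
      is_cis <- stats::runif(length(snp)) < cfg$cis_fraction
      probe_chrom <- character(length(snp))
      probe_pos <- integer(length(snp))
      if (any(is_cis)) {
        i <- which(is_cis)
        off <- round(stats::runif(length(i), -config$cis_window_bp,
                                  config$cis_window_bp))
        p <- pmin(pmax(universe$pos[snp[i]] + off, 1), .sim_chrom_len)
        probe_chrom[i] <- universe$chrom[snp[i]]
        probe_pos[i] <- as.integer(p)
      }
      if (any(!is_cis)) {
        i <- which(!is_cis)
        ch <- as.integer(universe$chrom[snp[i]])
        shift <- sample.int(.sim_n_chrom - 1L, length(i), replace = TRUE)
        probe_chrom[i] <- as.character((ch + shift - 1L) %% .sim_n_chrom + 1L)
        probe_pos[i] <- sample.int(.sim_chrom_len, length(i),
                                   replace = TRUE)
      }
      alpha <- ifelse(is_cis, config$cis_alpha, t_alpha)
      eqtl_p <- exp(stats::runif(length(snp), log(1e-12), log(alpha)))
      sig <- data.frame(
        rsid = universe$rsid[snp], tissue = rep(tissue, length(snp)),
        gene = sprintf("g%s.%04d", probe_chrom,
                       ceiling(probe_pos / 1e6)),
        probe_chrom = probe_chrom, probe_pos = probe_pos,
        eqtl_p = eqtl_p, stringsAsFactors = FALSE
      )
      dec_idx <- which(!flagged & stats::runif(nrow(universe)) <
                         cfg$decoy_rate)
      if (length(dec_idx)) {
        dcis <- stats::runif(length(dec_idx)) < cfg$cis_fraction
        dchrom <- ifelse(dcis, universe$chrom[dec_idx],
                         as.character(sample.int(.sim_n_chrom,
                                                 length(dec_idx),
                                                 replace = TRUE)))
        dpos <- ifelse(
          dcis,
          pmin(pmax(universe$pos[dec_idx] +
                      round(stats::runif(length(dec_idx),
                                         -config$cis_window_bp,
                                         config$cis_window_bp)), 1),
               .sim_chrom_len),
          sample.int(.sim_chrom_len, length(dec_idx), replace = TRUE)
        )
        dalpha <- ifelse(dcis, config$cis_alpha, t_alpha)
        # decoy P straddles (threshold, 1): never significant
        dp <- exp(stats::runif(length(dec_idx)) *
                    (log(1) - log(dalpha)) + log(dalpha))
        dec <- data.frame(
          rsid = universe$rsid[dec_idx],
          tissue = rep(tissue, length(dec_idx)),
          gene = sprintf("g%s.%04d", dchrom, ceiling(dpos / 1e6)),
          probe_chrom = dchrom, probe_pos = as.integer(dpos),
          eqtl_p = pmin(dp, 1), stringsAsFactors = FALSE
        )
        sig <- rbind(sig, dec)
      }
      rownames(sig) <- NULL
      sig
    })
    stats::setNames(out, cfg$tissues)
  })
}

#' Simulate a GWAS hit list with planted eQTL enrichment
#'
#' Draws `n_hits` SNPs without replacement from the universe by a
#' sequential weighted draw in which SNPs that are significant eQTLs in
#' `tissue` carry weight `enrichment_multiplier` and all others weight 1
#' (implemented by exponential sampling keys, which is distributionally
#' identical to successive weighted sampling).  `enrichment_multiplier = 1`
#' reduces to simple random sampling.  GWAS P-values are drawn uniform on
#' (0, `gwas_p_threshold`].
#'
#' @param universe a `snp_universe`.
#' @param eqtl_map output of [simulate_eqtl_map()].
#' @param tissue tissue whose eQTL status carries the planted weight.
#' @param cfg a [sim_config()].
#' @param config an [enrichment_config()].
#' @param analysis_label label for the resulting list.
#' @param seed seed override; defaults to `cfg$seed + 2`.
#' @return a `gwas_hits` object.
#' @export
simulate_gwas_hits <- function(universe, eqtl_map, tissue,
                               cfg = sim_config(),
                               config = enrichment_config(),
                               analysis_label = "sim",
                               seed = cfg$seed + 2L) {
  if (cfg$n_hits > nrow(universe)) {
    config_error("n_hits exceeds universe size")
  }
  sig <- significant_eqtl_rsids(eqtl_map[[tissue]], universe, tissue,
                                config)
  w <- ifelse(universe$rsid %in% sig, cfg$enrichment_multiplier, 1)
  with_seed(seed, {
    keys <- stats::rexp(nrow(universe)) / w   # Inf where w = 0: never drawn
    take <- order(keys)[seq_len(cfg$n_hits)]
    p <- stats::runif(cfg$n_hits, 0, config$gwas_p_threshold)
    new_gwas_hits(data.frame(rsid = universe$rsid[take], gwas_p = p,
                             stringsAsFactors = FALSE),
                  analysis_label)
  })
}

#' Simulate a full study bundle
#'
#' Generates the universe, the per-tissue eQTL tables, and one hit list
#' per analysis label, optionally writing everything in the package's
#' delimited formats plus a manifest recording the configuration and
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param config an [enrichment_config()].
#' @param out_dir if non-NULL, directory to write `snp_universe.tsv`,
#'   `eqtl_<tissue>.tsv`, `gwas_hits_<analysis>.tsv` and `manifest.json`.
#' @return list with `universe`, `eqtl_map`, `hit_lists` (named by
#'   analysis), and `cfg`.
#' @export
simulate_study <- function(cfg = sim_config(),
                           config = enrichment_config(),
                           out_dir = NULL) {
  universe <- simulate_universe(cfg)
  eqtl_map <- simulate_eqtl_map(universe, cfg, config)
  hit_lists <- lapply(seq_along(cfg$analyses), function(i) {
    simulate_gwas_hits(universe, eqtl_map, cfg$enrich_tissue, cfg, config,
                       analysis_label = cfg$analyses[i],
                       seed = cfg$seed + 2L + i)
  })
  names(hit_lists) <- cfg$analyses
  bundle <- list(universe = universe, eqtl_map = eqtl_map,
                 hit_lists = hit_lists, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(universe),
                       file.path(out_dir, "snp_universe.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (tissue in cfg$tissues) {
      utils::write.table(
        eqtl_map[[tissue]][, c("rsid", "gene", "probe_chrom",
                               "probe_pos", "eqtl_p")],
        file.path(out_dir, sprintf("eqtl_%s.tsv", tissue)),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    for (a in cfg$analyses) {
      utils::write.table(as.data.frame(hit_lists[[a]]),
                         file.path(out_dir,
                                   sprintf("gwas_hits_%s.tsv", a)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(config = unclass(cfg)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
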