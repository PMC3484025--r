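#' Classify a SNP-probe pair as cis or trans
#'
#' A SNP is a cis regulator of an expression probe when both lie on the
#' same chromosome and the SNP is within the cis window (default 4 Mb,
#' inclusive) of the probe site; every other configuration — including any
#' cross-chromosome pair, at any distance — is trans.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param snp_chrom,snp_pos SNP chromosome label(s) and 1-based position(s).
#' @param probe_chrom,probe_pos probe chromosome label(s) and position(s).
#' @param config an [enrichment_config()]; supplies `cis_window_bp`.
#' @return character vector of `"cis"` / `"trans"`.
#' @examples
#' cfg <- enrichment_config()
#' classify_regulation("1", 5e6, "1", 6e6, cfg)   # cis
#' classify_regulation("1", 1, "2", 1, cfg)       # trans
#' @export
classify_regulation <- function(snp_chrom, snp_pos, probe_chrom, probe_pos,
                                config = enrichment_config()) {
  if (any(snp_pos < 1) || any(probe_pos < 1)) {
    validation_error("positions must be >= 1")
  }
  assert_chrom(snp_chrom, "SNP chromosome")
  assert_chrom(probe_chrom, "probe chromosome")
  same <- normalize_chrom(snp_chrom) == normalize_chrom(probe_chrom)
  near <- abs(as.numeric(snp_pos) - as.numeric(probe_pos)) <=
    config$cis_window_bp
  ifelse(same & near, "cis", "trans")
}

#' Test eQTL significance under class-specific thresholds
#'
#' cis associations are significant at `eqtl_p < cis_alpha` (default 1e-4);
#' trans associations at `eqtl_p < trans_alpha_numerator / n_probes`
#' (default 0.05 / 25,834, a Bonferroni correction over expression probes).
#' Both comparisons are strict.
#'
#' @param eqtl_p numeric vector of association P-values in (0, 1].
#' @param regulation character vector of `"cis"` / `"trans"`.
#' @param config an [enrichment_config()].
#' @return logical vector.
#' @export
eqtl_significant <- function(eqtl_p, regulation,
                             config = enrichment_config()) {
  if (any(eqtl_p <= 0 | eqtl_p > 1)) {
    validation_error("eqtl_p must lie in (0, 1]")
  }
  if (!all(regulation %in% c("cis", "trans"))) {
    validation_error("regulation must be 'cis' or 'trans'")
  }
  ifelse(regulation == "cis",
         eqtl_p < config$cis_alpha,
         eqtl_p < trans_alpha(config))
}

#' Derive regulation class and significance for raw eQTL records
#'
#' Joins raw eQTL rows to the SNP universe for SNP coordinates, classifies
#' each SNP-probe pair as cis or trans, and applies the class-specific
#' significance threshold.  Records whose rsid is absent from the universe
#' cannot be classified (and could never be sampled into a null set); they
#' are dropped with a warning.
#'
#' @param records raw eQTL records from [read_eqtl_table()] or
#'   [simulate_eqtl_map()].
#' @param universe a `snp_universe`.
#' @param config an [enrichment_config()].
#' @return the records with `regulation` and `significant` columns added.
#' @export
classify_eqtl_records <- function(records, universe,
                                  config = enrichment_config()) {
  idx <- match(records$rsid, universe$rsid)
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sprintf(
      "%d eQTL record(s) for rsids absent from the universe were dropped",
      sum(miss)
    ))
    records <- records[!miss, , drop = FALSE]
    idx <- idx[!miss]
  }
  if (!nrow(records)) {
    records$regulation <- character(0)
    records$significant <- logical(0)
    return(records)
  }
  records$regulation <- classify_regulation(
    universe$chrom[idx], universe$pos[idx],
    records$probe_chrom, records$probe_pos, config
  )
  records$significant <- eqtl_significant(records$eqtl_p,
                                          records$regulation, config)
  rownames(records) <- NULL
  records
}

# distinct rsids with >= 1 significant eQTL record in the tissue
significant_eqtl_rsids <- function(records, universe, tissue, config) {
  rec <- records[records$tissue == tissue, , drop = FALSE]
  if (!nrow(rec)) return(character(0))
  rec <- classify_eqtl_records(rec, universe, config)
  unique(rec$rsid[rec$significant])
}

#' Annotate a GWAS hit list with significant eQTL evidence
#'
#' Inner-joins the hit list against the significant eQTL records of one
#' tissue.  Hits absent from the SNP universe are excluded (with a
#' warning) from both the annotation and the per-hit eQTL indicator, so
#' that the observed statistic and the resampling null share one frame.
#'
#' A SNP's eQTL status is a per-tissue boolean over distinct rsids: a SNP
#' that regulates several genes yields several annotation rows but counts
#' once in the indicator (and hence once in the enrichment statistic).
#'
#' @param hits a `gwas_hits` object.
#' @param eqtl_records raw eQTL records (any mix of tissues; filtered to
#'   `tissue`).
#' @param tissue tissue label to annotate against.
#' @param universe a `snp_universe`.
#' @param config an [enrichment_config()].
#' @return a list of class `annotated_hits`:
#'   \describe{
#'     \item{annotated}{data.frame with one row per
#'       (rsid, tissue, gene, analysis): columns `analysis`, `tissue`,
#'       `rsid`, `gene`, `regulation`, `eqtl_p`, `gwas_p`.}
#'     \item{is_eqtl}{named logical over the retained hit rsids.}
#'     \item{n_missing}{hits excluded for absence from the universe.}
#'   }
#' @export
annotate_hits <- function(hits, eqtl_records, tissue, universe,
                          config = enrichment_config()) {
  analysis <- attr(hits, "analysis_label") %||% "unspecified"
  in_univ <- hits$rsid %in% universe$rsid
  if (any(!in_univ)) {
    warning(sprintf(
      "%d hit(s) absent from the SNP universe excluded from analysis '%s'",
      sum(!in_univ), analysis
    ))
  }
  kept <- hits[in_univ, , drop = FALSE]

  rec <- eqtl_records[eqtl_records$tissue == tissue, , drop = FALSE]
  if (!nrow(rec)) {
    warning(sprintf("empty eQTL table for tissue '%s': all-false annotation",
                    tissue))
  }
  sig <- if (nrow(rec)) {
    rec <- classify_eqtl_records(rec, universe, config)
    rec[rec$significant, , drop = FALSE]
  } else {
    rec
  }

  ann <- merge(
    data.frame(rsid = kept$rsid, gwas_p = kept$gwas_p,
               stringsAsFactors = FALSE),
    sig[, intersect(c("rsid", "gene", "regulation", "eqtl_p"), names(sig)),
        drop = FALSE],
    by = "rsid"
  )
  if (nrow(ann)) {
    # collapse duplicate (rsid, gene) rows to the strongest evidence
    ann <- ann[order(ann$rsid, ann$gene, ann$eqtl_p), , drop = FALSE]
    ann <- ann[!duplicated(ann[c("rsid", "gene")]), , drop = FALSE]
  }
  annotated <- data.frame(
    analysis = rep(analysis, nrow(ann)),
    tissue = rep(tissue, nrow(ann)),
    rsid = ann$rsid, gene = ann$gene,
    regulation = ann$regulation,
    eqtl_p = ann$eqtl_p, gwas_p = ann$gwas_p,
    stringsAsFactors = FALSE
  )
  annotated <- annotated[order(annotated$rsid, annotated$gene), ,
                         drop = FALSE]
  rownames(annotated) <- NULL

  is_eqtl <- stats::setNames(kept$rsid %in% annotated$rsid, kept$rsid)
  structure(list(annotated = annotated, is_eqtl = is_eqtl,
                 n_missing = sum(!in_univ)),
            class = "annotated_hits")
}

#' @export
print.annotated_hits <- function(x, ...) {
  cat(sprintf(
    "annotated hits: %d eQTL row(s), %d of %d SNP(s) are eQTLs\n",
    nrow(x$annotated), sum(x$is_eqtl), length(x$is_eqtl)
  ))
  invisible(x)
}
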