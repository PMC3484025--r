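#' Pool annotated hit tables across analyses and tissues
#'
#' Concatenates per-analysis annotation tables, preserving the
#' (analysis, tissue) provenance of every row.  Accepts the data.frames
#' directly or the `annotated_hits` objects returned by [annotate_hits()].
#'
#' @param tables a list of annotation tables (or `annotated_hits`
#'   objects).
#' @return one data.frame; row count equals the sum of the inputs'.
#' @export
pool_annotated <- function(tables) {
  dfs <- lapply(tables, function(t) {
    if (inherits(t, "annotated_hits")) t$annotated else t
  })
  dfs <- dfs[vapply(dfs, nrow, 0L) > 0]
  if (!length(dfs)) {
    return(data.frame(analysis = character(0), tissue = character(0),
                      rsid = character(0), gene = character(0),
                      regulation = character(0), stringsAsFactors = FALSE))
  }
  cols <- Reduce(intersect, lapply(dfs, names))
  out <- do.call(rbind, lapply(dfs, function(d) d[, cols, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Per-SNP target-gene multiplicity
#'
#' Counts, for every distinct eQTL SNP in the pooled table, how many
#' distinct genes it targets, and tallies single-target vs multi-target
#' SNPs.  Percentages are taken over distinct SNPs, matching the
#' convention of reporting "unique eQTL SNPs".
#'
#' @param pooled pooled annotation table from [pool_annotated()].
#' @return list with `per_snp` (data.frame `rsid`, `n_genes`) and `totals`
#'   (list: `total_rows`, `distinct_snps`, `single_target`,
#'   `multi_target`, `pct_single`, `pct_multi`).
#' @export
snp_multiplicity <- function(pooled) {
  pairs <- unique(pooled[, c("rsid", "gene"), drop = FALSE])
  n_genes <- table(pairs$rsid)
  per_snp <- data.frame(rsid = names(n_genes),
                        n_genes = as.integer(n_genes),
                        stringsAsFactors = FALSE)
  per_snp <- per_snp[order(-per_snp$n_genes, per_snp$rsid), , drop = FALSE]
  rownames(per_snp) <- NULL
  distinct <- nrow(per_snp)
  single <- sum(per_snp$n_genes == 1L)
  multi <- distinct - single
  list(per_snp = per_snp,
       totals = list(
         total_rows = nrow(pooled),
         distinct_snps = distinct,
         single_target = single,
         multi_target = multi,
         pct_single = if (distinct) round(100 * single / distinct) else NA,
         pct_multi = if (distinct) round(100 * multi / distinct) else NA
       ))
}

#' SNP-level cis/trans breakdown
#'
#' Partitions single-target SNPs into cis vs trans, and multi-target SNPs
#' into all-cis / all-trans / mixed strata, over distinct
#' (rsid, gene, regulation) triples.  Strata are disjoint and exhaustive
#' within each group.
#'
#' @param pooled pooled annotation table with a `regulation` column.
#' @return list with `single` (counts `cis`, `trans`) and `multi` (counts
#'   `all_cis`, `all_trans`, `mixed`), each with integer-rounded
#'   percentages of its group.
#' @export
regulation_breakdown <- function(pooled) {
  trip <- unique(pooled[, c("rsid", "gene", "regulation"), drop = FALSE])
  per <- split(trip, trip$rsid)
  n_genes <- vapply(per, function(d) length(unique(d$gene)), 0L)
  cls <- vapply(per, function(d) {
    r <- unique(d$regulation)
    if (length(r) == 2L) "mixed" else r
  }, "")
  single <- cls[n_genes == 1L]
  multi <- cls[n_genes > 1L]
  pct <- function(k, n) if (n) round(100 * k / n) else NA
  list(
    single = list(cis = sum(single == "cis"),
                  trans = sum(single == "trans"),
                  pct_cis = pct(sum(single == "cis"), length(single)),
                  pct_trans = pct(sum(single == "trans"), length(single))),
    multi = list(all_cis = sum(multi == "cis"),
                 all_trans = sum(multi == "trans"),
                 mixed = sum(multi == "mixed"),
                 pct_all_cis = pct(sum(multi == "cis"), length(multi)),
                 pct_all_trans = pct(sum(multi == "trans"), length(multi)),
                 pct_mixed = pct(sum(multi == "mixed"), length(multi)))
  )
}

#' Collapse pooled annotations to gene-level summaries
#'
#' One row per distinct target gene: the tissues, analyses and regulation
#' classes it was implicated in, and the number of distinct SNPs
#' implicating it.  Sorted by SNP count descending; ties broken
#' lexicographically by gene label for deterministic output.
#'
#' @param pooled pooled annotation table.
#' @return a `gene_summary` data.frame with columns `gene`,
#'   `n_distinct_snps`, `n_analyses`, and list-columns `tissues`,
#'   `analyses`, `regulation`, `snp_rsids`.
#' @export
collapse_genes <- function(pooled) {
  if (!nrow(pooled)) {
    out <- data.frame(gene = character(0), n_distinct_snps = integer(0),
                      n_analyses = integer(0), stringsAsFactors = FALSE)
    out$tissues <- list(); out$analyses <- list()
    out$regulation <- list(); out$snp_rsids <- list()
    class(out) <- c("gene_summary", "data.frame")
    return(out)
  }
  per <- split(pooled, pooled$gene)
  genes <- names(per)
  snp_sets <- lapply(per, function(d) sort(unique(d$rsid)))
  out <- data.frame(
    gene = genes,
    n_distinct_snps = vapply(snp_sets, length, 0L),
    n_analyses = vapply(per, function(d) length(unique(d$analysis)), 0L),
    stringsAsFactors = FALSE
  )
  out$tissues <- lapply(per, function(d) sort(unique(d$tissue)))
  out$analyses <- lapply(per, function(d) sort(unique(d$analysis)))
  out$regulation <- lapply(per, function(d) sort(unique(d$regulation)))
  out$snp_rsids <- snp_sets
  out <- out[order(-out$n_distinct_snps, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("gene summary: %d gene(s)\n", nrow(x)))
  if (nrow(x)) {
    top <- utils::head(x, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s: %d SNP(s), %d analysis(es), %s\n",
                  top$gene[i], top$n_distinct_snps[i], top$n_analyses[i],
                  paste(top$regulation[[i]], collapse = "/")))
    }
    if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  }
  invisible(x)
}

#' Pairwise and all-way overlaps between labeled gene sets
#'
#' @param gene_sets named list (>= 2 entries) of character vectors;
#'   duplicates within a set are ignored.
#' @return list with `pairs` (data.frame: `set_a`, `set_b`, `n_a`, `n_b`,
#'   `n_intersection`, `pct_of_smaller`) and `all_way` (size of the
#'   intersection of every set).
#' @export
overlap_counts <- function(gene_sets) {
  if (length(gene_sets) < 2) {
    validation_error("overlap_counts needs at least two sets")
  }
  sets <- lapply(gene_sets, unique)
  labs <- names(sets)
  cmb <- utils::combn(seq_along(sets), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    ni <- length(intersect(sets[[a]], sets[[b]]))
    nm <- min(length(sets[[a]]), length(sets[[b]]))
    data.frame(set_a = labs[a], set_b = labs[b],
               n_a = length(sets[[a]]), n_b = length(sets[[b]]),
               n_intersection = ni,
               pct_of_smaller = if (nm) round(100 * ni / nm) else NA,
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, all_way = length(Reduce(intersect, sets)))
}

#' Two-sided Fisher's exact test for the overlap of two gene sets
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' (or less) than expected, via the exact hypergeometric distribution of
#' the 2x2 table.  Two-sided in the usual sense: the sum of the
#' probabilities of all tables no more likely than the observed one.
#'
#' The universe size is the number of genes either set *could* have
#' contained (e.g. distinct genes testable on the expression platform);
#' the P-value depends on it, so choose it deliberately.
#'
#' @param n_a,n_b set sizes.
#' @param n_intersection observed overlap.
#' @param universe_size size of the common gene universe.
#' @return two-sided P-value in (0, 1].
#' @examples
#' fisher_overlap(2, 2, 2, 4)  # 1/3
#' @export
fisher_overlap <- function(n_a, n_b, n_intersection, universe_size) {
  if (n_intersection > min(n_a, n_b) ||
      n_intersection < max(0, n_a + n_b - universe_size) ||
      max(n_a, n_b) > universe_size) {
    validation_error("inconsistent 2x2 overlap counts")
  }
  tab <- matrix(c(n_intersection, n_a - n_intersection,
                  n_b - n_intersection,
                  universe_size - n_a - n_b + n_intersection),
                nrow = 2)
  stats::fisher.test(tab)$p.value
}

#' Intersect gene-level results with an external gene list
#'
#' Case-insensitive symbol matching; duplicates in the external list are
#' removed (and counted) before intersecting.
#'
#' @param summary a `gene_summary` from [collapse_genes()], or a character
#'   vector of gene symbols.
#' @param external_genes character vector of external gene symbols.
#' @param external_label,summary_label labels for reporting.
#' @return list (class `overlap_report`) with `set_a_label`,
#'   `set_b_label`, `n_a`, `n_b`, `n_intersection`, `genes` (the matched
#'   symbols as labeled in the summary), and `n_duplicate_external`.
#' @export
gene_list_intersection <- function(summary, external_genes,
                                   external_label = "external",
                                   summary_label = "eQTL targets") {
  if (!length(external_genes)) {
    validation_error("external gene list must be non-empty")
  }
  own <- if (is.character(summary)) unique(summary) else summary$gene
  ext <- external_genes
  n_dup <- sum(duplicated(toupper(ext)))
  if (n_dup) {
    message(sprintf("gene_list_intersection: %d duplicate external symbol(s) removed",
                    n_dup))
  }
  ext <- ext[!duplicated(toupper(ext))]
  hit <- toupper(own) %in% toupper(ext)
  structure(list(set_a_label = summary_label, set_b_label = external_label,
                 n_a = length(own), n_b = length(ext),
                 n_intersection = sum(hit), genes = own[hit],
                 n_duplicate_external = n_dup),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap '%s' (n=%d) vs '%s' (n=%d): %d shared\n",
              x$set_a_label, x$n_a, x$set_b_label, x$n_b,
              x$n_intersection))
  if (length(x$genes)) cat("  ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
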