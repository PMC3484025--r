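#' Write an analysis result to disk
#'
#' Serializes a result as JSON with deterministic field order, plus
#' tab-separated companions for tabular parts (the null-count distribution
#' of an enrichment result; the flat table of a gene summary).
#' [read_report()] on the JSON path reproduces the object.
#'
#' @param x an `enrichment_result` or `gene_summary`.
#' @param path output path for the JSON file; companions are written next
#'   to it with derived names.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(x, path) UseMethod("write_report")

companion_path <- function(path, suffix) {
  paste0(sub("\\.json$", "", path), suffix)
}

check_writable <- function(path) {
  if (!dir.exists(dirname(path))) {
    ee_stop(sprintf("parent directory does not exist: %s", dirname(path)),
            "eqtlenrich_io_error")
  }
}

#' @export
write_report.enrichment_result <- function(x, path) {
  check_writable(path)
  tsv <- companion_path(path, "_null_counts.tsv")
  obj <- list(type = "enrichment_result",
              analysis_label = x$analysis_label, tissue = x$tissue,
              n_hits = x$n_hits, observed_count = x$observed_count,
              empirical_p = x$empirical_p, p_display = x$p_display,
              n_null_sets = x$n_null_sets, seed = x$seed,
              null_counts_file = basename(tsv))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(data.frame(null_count = x$null_counts), tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_report.gene_summary <- function(x, path) {
  check_writable(path)
  tsv <- companion_path(path, ".tsv")
  flat <- data.frame(
    gene = x$gene, n_distinct_snps = x$n_distinct_snps,
    n_analyses = x$n_analyses,
    tissues = vapply(x$tissues, paste, "", collapse = ","),
    analyses = vapply(x$analyses, paste, "", collapse = ","),
    regulation = vapply(x$regulation, paste, "", collapse = ","),
    snp_rsids = vapply(x$snp_rsids, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  obj <- list(type = "gene_summary", n_genes = nrow(x),
              table_file = basename(tsv))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result written by [write_report()]
#'
#' @param path path to the JSON file.
#' @return the reconstructed `enrichment_result` or `gene_summary`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "enrichment_result")) {
    tsv <- file.path(dirname(path), obj$null_counts_file)
    nc <- utils::read.delim(tsv)$null_count
    structure(list(analysis_label = obj$analysis_label,
                   tissue = obj$tissue,
                   n_hits = as.integer(obj$n_hits),
                   observed_count = as.integer(obj$observed_count),
                   null_counts = as.integer(nc),
                   empirical_p = obj$empirical_p,
                   p_display = obj$p_display,
                   n_null_sets = as.integer(obj$n_null_sets),
                   seed = as.integer(obj$seed)),
              class = "enrichment_result")
  } else if (identical(obj$type, "gene_summary")) {
    tsv <- file.path(dirname(path), obj$table_file)
    flat <- utils::read.delim(tsv, colClasses = "character")
    split_col <- function(x) {
      lapply(x, function(s) if (nzchar(s)) strsplit(s, ",")[[1]]
             else character(0))
    }
    out <- data.frame(gene = flat$gene,
                      n_distinct_snps = as.integer(flat$n_distinct_snps),
                      n_analyses = as.integer(flat$n_analyses),
                      stringsAsFactors = FALSE)
    out$tissues <- split_col(flat$tissues)
    out$analyses <- split_col(flat$analyses)
    out$regulation <- split_col(flat$regulation)
    out$snp_rsids <- split_col(flat$snp_rsids)
    class(out) <- c("gene_summary", "data.frame")
    out
  } else {
    format_error(sprintf("unrecognized report type in %s", path))
  }
}
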