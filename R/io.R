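#' Column-name dialect for delimited inputs
#'
#' Input tables come from heterogeneous sources, so every reader takes a
#' dialect mapping the canonical column names onto whatever the file calls
#' them.  The default assumes the canonical names themselves.
#'
#' @param rsid,chrom,pos,maf,gwas_p,gene,probe_chrom,probe_pos,eqtl_p source
#'   column name holding each canonical field.
#' @param sep field separator (default tab).
#' @return a named list of class `tsv_dialect`.
#' @examples
#' d <- tsv_dialect(rsid = "SNP", maf = "MAF")
#' @export
tsv_dialect <- function(rsid = "rsid", chrom = "chrom", pos = "pos",
                        maf = "maf", gwas_p = "gwas_p", gene = "gene",
                        probe_chrom = "probe_chrom",
                        probe_pos = "probe_pos", eqtl_p = "eqtl_p",
                        sep = "\t") {
  structure(list(rsid = rsid, chrom = chrom, pos = pos, maf = maf,
                 gwas_p = gwas_p, gene = gene, probe_chrom = probe_chrom,
                 probe_pos = probe_pos, eqtl_p = eqtl_p, sep = sep),
            class = "tsv_dialect")
}

# read a delimited file and pull out the canonical columns in `fields`;
# errors name the missing source column.  Returns a data.frame whose
# columns are canonically named, all read as character for per-field
# validation with line numbers (data line i is file line i + 1).
read_mapped <- function(path, dialect, fields) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, comment.char = "")
  out <- vector("list", length(fields))
  names(out) <- fields
  for (f in fields) {
    src <- dialect[[f]]
    if (!src %in% names(raw)) {
      format_error(sprintf(
        "missing column '%s' (mapped to canonical field '%s') in %s",
        src, f, path
      ))
    }
    out[[f]] <- raw[[src]]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# parse a character column as numeric; non-numeric entries are format
# errors reported with the file line number
parse_numeric <- function(x, field, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (!length(bad)) bad <- which(is.na(v))
  if (length(bad)) {
    format_error(sprintf(
      "non-numeric value '%s' for %s on line %d of %s",
      x[bad[1]], field, bad[1] + 1L, path
    ))
  }
  v
}

row_counts <- function(ingested, kept, dropped, rejected = 0L) {
  list(ingested = as.integer(ingested), kept = as.integer(kept),
       dropped = as.integer(dropped), rejected = as.integer(rejected))
}

#' Read a SNP-universe manifest
#'
#' The SNP universe is the full set of typed SNPs on the genotyping
#' platform: the sampling frame for the randomized null sets.  Each row
#' carries an rsID, chromosome, 1-based position and minor allele
#' frequency.
#'
#' @param path path to a delimited file with a header row.
#' @param dialect a [tsv_dialect()] mapping canonical columns to the file's.
#' @param platform_label label for the platform; defaults to the file name.
#' @return a `snp_universe`: a data.frame with columns `rsid`, `chrom`,
#'   `pos`, `maf`, a `platform_label` attribute, and a `row_counts`
#'   attribute recording ingested/kept/dropped/rejected tallies.
#' @export
read_snp_universe <- function(path, dialect = tsv_dialect(),
                              platform_label = NULL) {
  df <- read_mapped(path, dialect, c("rsid", "chrom", "pos", "maf"))
  df$pos <- parse_numeric(df$pos, "pos", path)
  df$maf <- parse_numeric(df$maf, "maf", path)
  bad <- which(df$maf < 0 | df$maf > 0.5)
  if (length(bad)) {
    validation_error(sprintf(
      "maf %g outside [0, 0.5] on line %d of %s",
      df$maf[bad[1]], bad[1] + 1L, path
    ))
  }
  bad <- which(df$pos < 1)
  if (length(bad)) {
    validation_error(sprintf("pos < 1 on line %d of %s", bad[1] + 1L, path))
  }
  u <- new_snp_universe(df,
                        platform_label %||%
                          sub("\\.[^.]*$", "", basename(path)))
  attr(u, "row_counts") <- row_counts(nrow(df), nrow(df), 0L)
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a SNP universe from a data.frame
#'
#' @param df data.frame with columns `rsid`, `chrom`, `pos`, `maf`.
#' @param platform_label platform label string.
#' @return a validated `snp_universe`.
#' @export
new_snp_universe <- function(df, platform_label = "unspecified") {
  if (!nrow(df)) validation_error("SNP universe must be non-empty")
  if (any(!nzchar(df$rsid))) validation_error("empty rsid in SNP universe")
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup)) {
    validation_error(sprintf(
      "duplicate rsid(s) in SNP universe (first offender: %s)", dup[1]
    ))
  }
  if (any(df$maf < 0 | df$maf > 0.5)) {
    validation_error("maf outside [0, 0.5] in SNP universe")
  }
  if (any(df$pos < 1)) validation_error("pos < 1 in SNP universe")
  assert_chrom(df$chrom)
  out <- data.frame(rsid = as.character(df$rsid),
                    chrom = normalize_chrom(df$chrom),
                    pos = as.integer(round(df$pos)),
                    maf = as.numeric(df$maf),
                    stringsAsFactors = FALSE)
  structure(out, platform_label = platform_label,
            class = c("snp_universe", "data.frame"))
}

#' @export
print.snp_universe <- function(x, ...) {
  cat(sprintf("SNP universe '%s': %d SNPs, MAF range [%.3f, %.3f]\n",
              attr(x, "platform_label"), nrow(x),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' Read a GWAS top-SNP list
#'
#' Reads rsID + association P-value pairs and applies the inclusion
#' threshold at read time: rows with `gwas_p` above the threshold are
#' dropped (and counted), because upstream lists cannot be trusted to be
#' pre-filtered.
#'
#' @param path delimited file with columns for rsid and GWAS P-value.
#' @param dialect a [tsv_dialect()].
#' @param threshold inclusion threshold; rows with `gwas_p > threshold` are
#'   dropped.  Default 1e-3.
#' @param analysis_label label of the primary analysis the list came from;
#'   defaults to the file name.
#' @return a `gwas_hits` data.frame with columns `rsid`, `gwas_p`, an
#'   `analysis_label` attribute and a `row_counts` attribute.
#' @export
read_gwas_hits <- function(path, dialect = tsv_dialect(),
                           threshold = 1e-3, analysis_label = NULL) {
  if (threshold <= 0 || threshold > 1) {
    config_error("threshold must lie in (0, 1]")
  }
  df <- read_mapped(path, dialect, c("rsid", "gwas_p"))
  df$gwas_p <- parse_numeric(df$gwas_p, "gwas_p", path)
  bad <- which(df$gwas_p <= 0 | df$gwas_p > 1)
  if (length(bad)) {
    validation_error(sprintf(
      "gwas_p outside (0, 1] on line %d of %s", bad[1] + 1L, path
    ))
  }
  ingested <- nrow(df)
  keep <- df$gwas_p <= threshold
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (dropped) {
    message(sprintf("read_gwas_hits: dropped %d of %d rows above P = %g",
                    dropped, ingested, threshold))
  }
  if (!nrow(df)) warning(sprintf("no hits at or below P = %g in %s",
                                 threshold, path))
  hits <- new_gwas_hits(df, analysis_label %||%
                          sub("\\.[^.]*$", "", basename(path)))
  attr(hits, "row_counts") <- row_counts(ingested, nrow(df), dropped)
  hits
}

#' Construct a GWAS hit list from a data.frame
#'
#' @param df data.frame with columns `rsid`, `gwas_p`.
#' @param analysis_label label of the originating primary analysis.
#' @return a validated `gwas_hits` object.
#' @export
new_gwas_hits <- function(df, analysis_label = "unspecified") {
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup)) {
    validation_error(sprintf(
      "duplicate rsid(s) in hit list (first offender: %s)", dup[1]
    ))
  }
  out <- data.frame(rsid = as.character(df$rsid),
                    gwas_p = as.numeric(df$gwas_p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, analysis_label = analysis_label,
            class = c("gwas_hits", "data.frame"))
}

#' @export
print.gwas_hits <- function(x, ...) {
  cat(sprintf("GWAS hit list '%s': %d SNPs\n",
              attr(x, "analysis_label"), nrow(x)))
  invisible(x)
}

#' Read a per-tissue eQTL association table
#'
#' Raw SNP-to-gene association rows for one tissue.  Regulation class
#' (cis/trans) and significance are *not* derived here; that is the
#' annotation step's job ([classify_eqtl_records()]).  Duplicate
#' (rsid, gene) rows are kept with a warning — deduplication happens at
#' summary time, where "unique" is defined.
#'
#' @param path delimited file with rsid, gene, probe location and eQTL
#'   P-value columns.
#' @param dialect a [tsv_dialect()].
#' @param tissue tissue label to tag every record with.
#' @return a data.frame of raw eQTL records with columns `rsid`, `tissue`,
#'   `gene`, `probe_chrom`, `probe_pos`, `eqtl_p` and a `row_counts`
#'   attribute.
#' @export
read_eqtl_table <- function(path, dialect = tsv_dialect(), tissue) {
  df <- read_mapped(path, dialect,
                    c("rsid", "gene", "probe_chrom", "probe_pos", "eqtl_p"))
  df$probe_pos <- parse_numeric(df$probe_pos, "probe_pos", path)
  df$eqtl_p <- parse_numeric(df$eqtl_p, "eqtl_p", path)
  bad <- which(df$eqtl_p <= 0 | df$eqtl_p > 1)
  if (length(bad)) {
    validation_error(sprintf(
      "eqtl_p outside (0, 1] on line %d of %s (P = 0 is rejected, not clamped)",
      bad[1] + 1L, path
    ))
  }
  assert_chrom(df$probe_chrom, "probe chromosome")
  ndup <- sum(duplicated(df[c("rsid", "gene")]))
  if (ndup) {
    warning(sprintf("%d duplicate (rsid, gene) row(s) in %s; kept as-is",
                    ndup, path))
  }
  out <- data.frame(rsid = as.character(df$rsid),
                    tissue = tissue,
                    gene = as.character(df$gene),
                    probe_chrom = normalize_chrom(df$probe_chrom),
                    probe_pos = as.integer(round(df$probe_pos)),
                    eqtl_p = df$eqtl_p,
                    stringsAsFactors = FALSE)
  attr(out, "row_counts") <- row_counts(nrow(df), nrow(out), 0L)
  out
}
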