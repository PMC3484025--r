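# small in-code fixtures shared across test files

make_universe <- function(df) new_snp_universe(df)

# a tiny deterministic universe: 20 SNPs, two chromosomes, two MAF bins
tiny_universe <- function() {
  new_snp_universe(data.frame(
    rsid = sprintf("rs%02d", 1:20),
    chrom = rep(c("1", "2"), each = 10),
    pos = seq(1e6, 20e6, by = 1e6),
    maf = rep(c(0.02, 0.30), times = 10),
    stringsAsFactors = FALSE
  ), platform_label = "tiny")
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# raw eQTL record rows (builder keeps tests terse)
eqtl_rows <- function(rsid, gene, probe_chrom, probe_pos, eqtl_p,
                      tissue = "parietal") {
  data.frame(rsid = rsid, tissue = rep_len(tissue, length(rsid)),
             gene = gene,
             probe_chrom = rep_len(as.character(probe_chrom),
                                   length(rsid)),
             probe_pos = as.integer(probe_pos), eqtl_p = eqtl_p,
             stringsAsFactors = FALSE)
}

hits_of <- function(rsids, label = "test",
                    gwas_p = rep(5e-4, length(rsids))) {
  new_gwas_hits(data.frame(rsid = rsids, gwas_p = gwas_p,
                           stringsAsFactors = FALSE), label)
}
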