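Package: eqtlenrich
Title: eQTL Enrichment Testing for Top GWAS Signals with MAF-Matched
    Resampling Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates top single-nucleotide polymorphisms (SNPs) from a
    genome-wide association study with tissue-specific expression
    quantitative trait locus (eQTL) evidence, classifies each SNP-gene
    association as cis (within a 4 Mb window of the expression probe) or
    trans with class-specific significance thresholds, and tests whether
    the hit list carries more eQTL SNPs than expected by drawing
    randomized SNP sets from the genotyping platform matched on minor
    allele frequency, yielding an empirical enrichment P-value.  Includes
    gene-level collapsing of eQTL targets, cross-tissue and cross-analysis
    overlap summaries with Fisher's exact tests, and a synthetic-data
    generator with a controllable planted enrichment for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
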