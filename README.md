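# eqtlenrich

Tests whether the top SNPs of a genome-wide association study (GWAS) are
enriched for tissue-specific expression quantitative trait loci (eQTLs),
using randomized SNP sets matched on minor allele frequency (MAF) as the
null. It is aimed at analysts doing functional annotation of GWAS
results: SNPs below genome-wide significance are individually
unreliable, but if they carry more regulatory variants than
frequency-matched random SNPs from the same genotyping platform, the
signal set as a whole is biologically loaded.

## The statistic

Each SNP-to-probe association in a tissue's eQTL table is classified as
**cis** (same chromosome, within 4 Mb of the probe site, inclusive) or
**trans** (everything else), and called significant at *P* < 10⁻⁴ (cis)
or *P* < 0.05/25,834 (trans; Bonferroni over expression probes). A hit
SNP "is an eQTL" when it has at least one significant association; a
multi-gene regulator counts once.

For a hit list **L** with observed eQTL SNP count *n_obs*, the package
draws *N* randomized sets (default 1,000) from the platform's SNP
universe, each reproducing **L**'s tally over 5% MAF bins exactly
(uniform within-bin sampling without replacement), scores each set with
the identical counting rule, and reports the empirical enrichment
P-value

> *P* = #{ sets with count ≥ *n_obs* } / *N*,

displayed as `<1/N` when no set reaches the observed count.
Descriptive summaries — SNP multiplicity, cis/trans strata, gene-level
collapsing, cross-tissue overlaps with Fisher's exact test — complete
the picture. A synthetic-data generator with a plantable enrichment
odds multiplier θ supports calibration and power studies end to end.

## Worked example

```r
library(eqtlenrich)

# synthetic study: 20,000-SNP platform, 300-SNP hit lists, eQTL SNPs
# entering the parietal hit lists with 3x odds
scfg <- sim_config(n_universe = 20000, n_hits = 300,
                   tissues = c("parietal", "lcl"),
                   analyses = c("SpecAll", "StrictAll"),
                   enrichment_multiplier = 3, enrich_tissue = "parietal",
                   seed = 42)
bundle <- simulate_study(scfg)

cfg <- enrichment_config(n_null_sets = 1000, seed = 1)
run_enrichment(bundle$hit_lists$SpecAll, bundle$eqtl_map$parietal,
               "parietal", bundle$universe, cfg)
#> eQTL enrichment: analysis 'SpecAll', tissue 'parietal'
#>   observed eQTL SNPs: 44 of 300 hits
#>   null mean 15.05 (sd 3.72) over 1000 MAF-matched sets
#>   enrichment P = <0.001

run_enrichment(bundle$hit_lists$SpecAll, bundle$eqtl_map$lcl,
               "lcl", bundle$universe, cfg)
#> eQTL enrichment: analysis 'SpecAll', tissue 'lcl'
#>   observed eQTL SNPs: 17 of 300 hits
#>   null mean 15.89 (sd 3.84) over 1000 MAF-matched sets
#>   enrichment P = 0.434
```

The planted 3× enrichment lifts the parietal count (44) far above its
MAF-matched null (15.1 ± 3.7): none of 1,000 randomized sets reached
it, so the empirical P is reported as `<0.001`. The LCL tissue, where
nothing was planted, sits inside its null (P = 0.434).

Descriptive summaries pool the annotated lists:

```r
ann <- lapply(names(bundle$hit_lists), function(a)
  annotate_hits(bundle$hit_lists[[a]], bundle$eqtl_map$parietal,
                "parietal", bundle$universe, cfg))
pooled <- pool_annotated(ann)
snp_multiplicity(pooled)$totals
#> $total_rows    98
#> $distinct_snps 84
#> $single_target 72
#> $multi_target  12
#> $pct_single    86
#> $pct_multi     14
```

Of the 84 distinct eQTL SNPs pooled across the two analyses, 86%
regulate a single gene; `collapse_genes(pooled)` ranks the target genes
by the number of distinct implicating SNPs, and `write_report()`
serializes any result as JSON with TSV companions.

Real data enter through `read_snp_universe()`, `read_gwas_hits()`
(which applies the P ≤ 10⁻³ inclusion threshold at read time) and
`read_eqtl_table()`, each taking a `tsv_dialect()` that maps your
column names onto the canonical ones. A thin command-line front end
(`inst/cli/eqtlenrich.R`) exposes `simulate`, `annotate`, `enrich` and
`summarize` subcommands.

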