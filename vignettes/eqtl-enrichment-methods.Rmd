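---
title: "Methods: MAF-matched eQTL enrichment testing for top GWAS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAF-matched eQTL enrichment testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the pipeline answers

A genome-wide association study (GWAS) of a complex trait typically
yields many sub-genome-wide-significant SNPs (for example, everything at
P < 10^-3). Individually these are unreliable; collectively they may
still be biologically loaded. One way to ask whether they are is
functional annotation: if the top SNPs are enriched for expression
quantitative trait loci (eQTLs) — variants associated with transcript
abundance — in a disease-relevant tissue, the signal set as a whole is
more likely to be regulatory rather than noise.

`eqtlenrich` implements that test. Given (a) a hit list of top GWAS
SNPs, (b) a per-tissue table of SNP-to-gene expression associations, and
(c) the manifest of all SNPs typed on the genotyping platform (the
*SNP universe*), it counts how many hit SNPs are significant eQTLs in
the tissue and compares that count with the distribution obtained from
randomized SNP sets drawn from the universe, matched to the hit list on
minor allele frequency (MAF).

## eQTL annotation rules

Each SNP-to-probe association is classified by distance:

* **cis** — SNP and expression probe on the same chromosome and at most
  `cis_window_bp` apart (default 4,000,000 bp, inclusive);
* **trans** — everything else, including all cross-chromosome pairs.

Significance is class-specific and strict:

* cis: `eqtl_p < cis_alpha` (default 10^-4);
* trans: `eqtl_p < trans_alpha_numerator / n_probes` (default
  0.05 / 25,834 ≈ 1.94 × 10^-6, a Bonferroni correction over the
  expression probes of the profiling platform).

The window is taken as inclusive at exactly 4 Mb: the plain reading of
"within", with cross-chromosome pairs trans by convention. The probe is
located by a single coordinate (`probe_pos`); whether that is a probe
start or midpoint is up to the data provider, since the upstream eQTL
table defines it.

A SNP *is an eQTL* in a tissue when it has at least one significant
association there. This statistic is deliberately a boolean over
distinct rsids: a SNP regulating three genes contributes three
annotation rows but one eQTL SNP, in both the observed count and the
null counts. Counting SNP-gene pairs instead would let a handful of
multi-target SNPs dominate the test.

## The MAF-matched resampling null

Rarer SNPs have less statistical power in eQTL mapping, so eQTL status
correlates with MAF. A naive random-SNP null would therefore be biased.
The null here conditions on MAF:

1. every universe SNP is assigned to a MAF bin of width `bin_width`
   (default 5%, ten bins over (0, 0.5]);
2. the hit list's per-bin tally (its *bin profile*) is computed;
3. each of `n_null_sets` (default 1,000) randomized sets draws exactly
   that many SNPs per bin, uniformly without replacement within the set;
4. each set is scored with the identical distinct-SNP eQTL count;
5. the *empirical enrichment P-value* is the proportion of sets whose
   count **matches or exceeds** the observed count.

Numerical and procedural choices, and why:

* **Bins are left-closed, right-open**, with the top bin closed so
  MAF = 0.5 is representable; bin indices are zero-based
  (`assign_maf_bin(0.05)` is bin 1). Ratios sitting on a bin boundary
  are snapped within 10^-9 before flooring, so binary floating-point
  jitter (0.15/0.05 evaluating just under 3) cannot misbin.
* **Observed hit SNPs stay in the sampling frame.** Excluding them
  would tilt the null slightly anticonservative; nothing in the
  procedure requires it.
* **The same SNP may appear in different null sets** — sets are
  independent replicates, only within-set draws are without
  replacement.
* **Ties count against enrichment** ("matches or exceeds"), making the
  P-value valid but conservative for very discrete counts.
* **Zero exceedances** are reported as the proportion 0.0 with display
  string `"<1/N"` (`"<0.001"` at N = 1,000); no +1 pseudo-count is
  added, matching the stated definition of the statistic.
* **Reproducibility**: one master seed per run; the per-set draws
  consume one sequential RNG stream, so identical seed + inputs give
  bit-identical null counts, and exact per-bin matching of every set is
  asserted on every run.
* **Each tissue × analysis combination is tested independently**, with
  no cross-test multiplicity correction and a freshly drawn null per
  run.

## Descriptive summaries

After annotation, per-analysis tables are pooled with provenance and
summarized: per-SNP target multiplicity (single- vs multi-target SNPs),
SNP-level cis/trans strata (all-cis / all-trans / mixed for multi-target
SNPs), gene-level collapsing (distinct implicating SNPs per gene, with
lexicographic tie-breaks for deterministic ranking), pairwise and
all-way overlaps of per-tissue gene sets, and intersection with
external gene lists (case-insensitive symbol matching).

Set overlaps can be tested with `fisher_overlap()`, a two-sided exact
test on the 2×2 table; "two-sided" means the sum of the probabilities of
all tables no more likely than the observed one (the common convention,
stated explicitly because conventions differ). The gene universe for
this test is **not** derivable from the inputs — it should be the number
of genes the expression platform could have implicated, and the P-value
depends on it, so it is an explicit argument.

## The synthetic-data generator

Because the original inputs (GWAS additional files, tissue eQTL maps
from repository accessions, the array manifest) cannot be bundled, the
package ships a generator that emulates their statistical structure:

* a SNP universe with configurable MAF distribution (uniform on
  [0.01, 0.5] by default; a rescaled Beta is available) over 22
  synthetic 250 Mb autosomes — large enough to exercise the 4 Mb cis
  window and cross-chromosome trans cases;
* per-tissue binary eQTL status with base rate `eqtl_base_rate`
  (scalar, or per-MAF-bin to emulate power-driven MAF dependence),
  multi-gene targets at rate `multi_gene_rate` (default 0.16), cis
  class at `cis_fraction` (default 0.58); significant rows get
  P-values log-uniform between 10^-12 and the class threshold, and
  unflagged SNPs can receive decoy rows log-uniform between the
  threshold and 1, so both sides of each cutoff are exercised — the
  exact P distribution is irrelevant to the binary statistic, only the
  straddling matters;
* hit lists drawn without replacement with odds multiplier
  `enrichment_multiplier` (θ) for eQTL SNPs, via exponential sampling
  keys — distributionally identical to sequential weighted draws, and
  θ = 1 reduces exactly to simple random sampling. Enrichment is
  planted in the sampling of hits, not by inflating eQTL rates among
  hits post hoc, because that keeps the universe's annotation fixed —
  matching the real workflow, where eQTL mapping precedes the GWAS
  list.

Default sizes (50,000-SNP universe, 500-SNP hit lists, 5% base rate)
are a desk-scale platform: large enough that bin-matched sampling,
power and calibration behave as they would on a real array, small
enough to simulate hundreds of replicate studies in minutes.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: linkage disequilibrium between
SNPs (real hit lists are clumps of correlated SNPs, so their effective
size is smaller than their count), overlap and nesting between primary
analyses, imputation quality filtering, gene length and density
structure, and any covariate of eQTL status other than MAF. The test's
validity on real data rests on MAF being the dominant confounder; the
package matches on MAF only, as the original design did.

## Validation strategy and problem sizes

The test suite checks, among other things:

* exact per-bin matching of every generated null set;
* agreement of the empirical P with brute-force enumeration of all
  bin-respecting subsets on a 20-SNP universe;
* inclusion frequencies of matched sampling against the closed-form
  binomial;
* equality of `fisher_overlap()` with direct hypergeometric enumeration
  over all small 2×2 tables (exhaustive to universe 40, systematically
  subsampled to 60);
* calibration: across 200 simulated null studies (θ = 1) at the default
  scale with 500 null sets each, the rejection rate at α = 0.05 must
  lie inside the exact binomial 99% acceptance band;
* power: rejection rate ≥ 0.8 at θ = 4, and median empirical P
  decreasing in θ. At the full default scale, power saturates already
  at θ = 2 (observed counts sit ~5 null standard deviations above the
  null mean), so the θ = 2 and θ = 4 medians both hit the resolution
  floor 0 and the strict ordering between them cannot be observed
  there; the strictly decreasing trend is demonstrated at a smaller
  scale (4,000-SNP universe, 80-SNP lists) where θ = 2 gives partial
  power;
* approximate uniformity of the null empirical P (Kolmogorov–Smirnov,
  α = 0.01) at a scale where expected counts are large enough that the
  discreteness of the matches-or-exceeds statistic does not dominate;
* the descriptive summaries against a deterministic synthetic pooled
  table whose marginal counts are fixed by construction and self-checked
  independently of the summarize code.

Statistical tests use fixed seeds and tolerances stated in standard
errors (3–4 SE, or exact binomial bands), chosen before the tests were
first run.

## Known limitations

* No LD-aware null: enrichment P-values on real, LD-clumped hit lists
  are anti-conservative to a degree the package cannot quantify.
* Matching is on MAF alone; distance-to-gene or gene-density matching
  is not implemented.
* The cis window is a single symmetric cutoff to one probe coordinate;
  probe-to-gene remapping and transcript structure are out of scope.
* eQTL discovery itself (from genotype and expression matrices) is out
  of scope — the package consumes association tables.
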