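# metachip

Metagene ("average gene") analysis of ChIP-chip tiling-array data, built
for the classic fission-yeast experimental design: probes every ~200 bp
across the genome, one enrichment track per antibody × strain, and
questions about how a factor's distribution *within* genes changes
between conditions.

## What it computes

The central object is the **profile matrix**: each gene's probe-level
log2(IP/input) values are mapped, strand-aware, into a scaled coordinate
`x ∈ [0, 1]` spanning 5′ flank → coding region → 3′ flank, then averaged
into 50 position bins. On top of it the package provides:

- **Occupancy quartiles.** Genes are ranked by their total coding-region
  RNAPII enrichment in a *reference* condition and split into four
  equal classes (Q1 low … Q4 high); a mutant is stratified by the
  wild-type ranking so its classes are comparable.
- **Difference profiles with tiered significance.** Per quartile and
  position, the per-gene differences `mutant − wild type` are tested
  against zero with a one-sample t-test
  (`t = m̄ / (s/√n)`, df = n − 1, two-sided), and each position is
  shaded by tier: open (p > 0.01), light (10⁻⁵ < p ≤ 0.01), dark
  (p ≤ 10⁻⁵). This is the machinery behind "downstream 3′ shift"
  claims: a 5′ decrease with a significant 3′ increase.
- **Mark normalization and correlation.** Cell-wise log2 subtraction of
  a reference track (e.g. modified H2B minus total H2B) and the
  genome-wide Pearson correlation of two marks' gene-level totals.
- **Ranked occupancy changes and enrichment.** The genes with the
  largest mean coding-region increases/decreases, and one-sided
  hypergeometric over-representation of categories in such lists
  (`P(X ≥ k)` for k of n selected genes in a K-of-N category), plus
  list-versus-occupancy-class overlap tests.
- **ChIP-qPCR quantification.** Percent input
  (`100 · IP / (input / input_fraction)`), per-replicate ratio
  normalization, replicate mean ± sd, and Welch unpaired t-tests with
  the `*` p < 0.04 / `**` p < 0.02 star convention.
- **A synthetic-data generator** that emulates the whole design —
  tiled probes, occupancy classes, a 5′-biased shape with a hinged
  3′-shift effect, a correlated companion mark, replicate qPCR noise —
  so every stage is testable without external data.

All user-facing functions take and return tibbles and compose with the
pipe; results plot with `plot_average_profile()`,
`plot_difference_profile()` and `autoplot()`.

## Worked example

```r
library(metachip)

cfg   <- sim_config(n_genes = 200, seed = 42)
genes <- simulate_genome(cfg)
wt    <- simulate_occupancy(genes, cfg, delta = 0,   seed = 43)
mut   <- simulate_occupancy(genes, cfg, delta = 0.3, amp5 = 0.2, seed = 44)

mat_wt  <- build_profile_matrix(assign_probes(genes, wt),  50, gene_ids = genes$gene_id)
mat_mut <- build_profile_matrix(assign_probes(genes, mut), 50, gene_ids = genes$gene_id)
glance(mat_wt)
#>   n_genes n_bins prop_missing mean_value
#> 1     200     50        0.733       1.12

groups <- group_by_quartile(gene_total_enrichment(genes, wt))
table(groups$quartile)
#> Q1 Q2 Q3 Q4
#> 50 50 50 50

dp <- positionwise_ttest(difference_matrix(mat_mut, mat_wt), groups)
dplyr::count(dp, group, tier)
#>   group tier      n
#> 1 Q1    light     5
#> 2 Q1    open     45
#> 3 Q2    light     6
#> ...
```

`prop_missing ≈ 0.73` reflects the sparse tiling: with one probe per
~200 bp and 50 bins per gene, most gene × bin cells hold no probe and
stay missing rather than being imputed. Each quartile holds exactly 50
of the 200 genes. In the difference profile, the light-tier positions
(p ≤ 0.01) concentrate at 3′ ends of the gene body — the simulated
downstream shift — while most positions stay open (null). A companion
mark simulated at `mark_rho = 0.58` is recovered at the gene level:

```r
mark <- simulate_correlated_mark(genes, cfg, seed = 45)
mark_correlation(gene_total_enrichment(genes, wt),
                 gene_total_enrichment(genes, mark))
#>       r     n
#> 1 0.473   200
```

(With 200 genes the sampling error on r is large; at the 2000-gene
scale used in the acceptance script the estimate lands within a few
hundredths of the target.)

`run_pipeline(list(seed = 1), "out/")` chains all of the above —
simulate → profile → quartiles → difference/t-tests → correlation →
ranked changes → enrichment — writing plain TSV tables plus a JSON
manifest; identical config and seed give byte-identical outputs.

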