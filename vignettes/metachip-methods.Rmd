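---
title: "Methods: metagene profiling and differential occupancy for tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metagene profiling and differential occupancy for tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachip)
```

## The problem

Genome tiling microarrays measure ChIP enrichment as a log2(IP/reference)
ratio for one ~50 bp probe every ~200 bp. That resolution is far too
coarse to say anything about an individual gene's internal occupancy
profile, but averaging thousands of genes in a common scaled coordinate
— the "average gene" or metagene — turns it into a sensitive readout of
*where* within genes a factor sits, and how that changes between a
wild-type and a mutant strain. This package implements that analysis:
profile construction, occupancy-class stratification, position-wise
differential statistics with tiered shading, mark-to-mark normalization
and correlation, ranked-change gene lists with over-representation
tests, and the matching ChIP-qPCR arithmetic for single-locus
validation.

## Coordinates and binning

Internally every interval is 0-based half-open, matching BED; GFF3
input (1-based closed) is converted on read. Probes are strandless —
tiling arrays interrogate both strands — while genes carry strand.

A probe belongs to a gene when its midpoint lies in
`[start − flank_bp, end + flank_bp)`. Midpoint membership, rather than
overlap fraction, is the standard choice for sparse tiling designs: it
is unambiguous and every probe counts at most once. When flank
extensions of two genes both capture a midpoint, the probe goes to the
gene whose coding region is nearer; an exact tie drops the probe, so
no probe is double-counted in difference statistics.

The scaled coordinate `x ∈ [0, 1]` runs 5′→3′ (minus-strand genes are
mirrored) and is **piecewise linear**: the 5′ flank maps onto
`[0, 0.1)`, the coding region onto `[0.1, 0.9)`, the 3′ flank onto
`[0.9, 1]` under the default `bin_layout = c(0.1, 0.8, 0.1)`. A single
linear map over the whole extended span cannot give a fixed
flank/coding bin split when flank length is constant but gene lengths
vary, so the scale-regions convention used by metagene tools generally
is adopted here. With `flank_bp = 0` the layout collapses to
`(0, 1, 0)` and `x` spans the coding region alone. Bin `j` of
`n_bins = 50` covers `x ∈ [(j−1)/n, j/n)` with the last bin closed;
`findInterval()` implements exactly those comparisons, so binning is
bit-reproducible against a brute-force loop. Cells without probes are
missing (`NA`), never imputed, and every downstream mean, t-test and
count handles missingness per cell.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 50 | positions along the average gene |
| `bin_layout` | (0.1, 0.8, 0.1) | fraction of bins for 5′ flank / coding / 3′ flank; the split of the 50 positions is not dictated by the data, so it is configurable |
| `flank_bp` | 300 bp | ≳1.5 probe spacings beyond the UTR; enough to see boundary behavior without swallowing neighbors |
| `min_probes` | 5 | coding probes required for a gene to enter analyses; at 200 bp tiling this keeps genes ≳1 kb and stops single-probe genes from dominating bin statistics |

## Quartile stratification

Genes are ranked by mean coding-region enrichment in a **reference**
condition (wild type), split into four equal classes — remainders go to
the lower quartiles, ties break by `gene_id`, so the grouping is exactly
reproducible — and the labels are copied onto any other condition. That
reference-anchored grouping is what makes mutant and wild-type class
curves comparable: a gene does not migrate between classes because the
mutation changed its occupancy.

## Position-wise tests and tiers

The difference matrix is per-gene `mutant − wild type`, cell-wise, over
the gene intersection. For each (quartile, bin) the non-missing
differences give `t = m̄/(s/√n)` with the sample sd and df = n − 1,
two-sided. This is deliberately a one-sample test on paired-by-gene
differences — pairing removes between-gene baseline variance — so no
Welch correction applies here. Conventions for the edges:

- `n < 3`: the cell is *degenerate* — rendered as a gap, no p-value.
  A t-test is undefined below n = 2 and unstable at n = 2.
- `s = 0, m̄ = 0`: the exact null, t = 0, p = 1.
- `s = 0, m̄ ≠ 0`: degenerate, displayed in the strongest tier (the
  evidence is infinite under the model, but no finite p is meaningful).
- Tier boundaries are closed on the significant side: p = 0.01 is
  light, p = 10⁻⁵ is dark. The plotting key uses strict inequalities
  in both directions, so a convention is required; this one is fixed
  and tested.

No multiple-testing correction is applied across the 4 × 50 cells by
default — the tier display is a raw-p convention — but
Benjamini–Hochberg is available where lists of categories are tested
(`category_enrichment(adjust = TRUE)`).

## Correlation, ranked changes, enrichment

Mark–mark correlation is the Pearson r of gene-level totals over genes
assignable in both conditions, with n reported. The per-gene change
score is the mean over non-missing *coding* bins of the difference
matrix (flanks are excluded: within-gene redistribution claims concern
the gene body); the top-n most positive and most negative scores form
the increase/decrease lists, ties broken by `gene_id`.

Over-representation uses the one-sided upper hypergeometric tail
`P(X ≥ k)`, computed by `stats::phyper` (log-space internally, exact
for small N) and verified in the tests against complete enumeration of
draws for all universes up to N = 25. Categories are a flat two-column
gene→category file; no ontology graph is consulted, and the universe is
an explicit argument — whether "all array genes" or "all annotated
genes" is the right null is a scientific choice the caller must make,
so the package refuses to default it.

## ChIP-qPCR

Inputs are linear signal quantities (post standard curve). Percent
input is `100 · IP/(input/input_fraction)`; the aliquot fraction
defaults to 1 and is an explicit column because dilution-correction
practice varies. Ratio normalization (e.g. phospho-epitope over total
protein) is computed per replicate and then averaged — not as a ratio
of means — so replicate error bars remain meaningful. Condition
comparisons use the Welch unequal-variance t-test: with three
independent experiments per arm, assuming equal variances buys little
and risks anticonservatism. Stars follow `*` p < 0.04, `**` p < 0.02
(strict). Degenerate inputs (n < 2, or zero variance with equal means)
report p = 1 with no stars instead of erroring, so batch summaries of
many primer pairs survive a flat target.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions; the generator is a
pure function of (config, seed) via `withr::with_seed`, and every
output is byte-reproducible.

- **Layout**: `n_genes = 540` genes (the cohort size of a typical
  average-gene figure), lengths uniform on 1200–3000 bp, random strand,
  intergenic gaps 700–1400 bp, at most 500 genes per chromosome.
- **Classes**: round-robin assignment to 4 occupancy classes with
  baselines `class_levels = (0.4, 0.9, 1.5, 2.2)` log2 units plus
  per-gene jitter `level_sd = 0.2` — spanning the low-to-high range
  tiling arrays report, and giving quartile recovery something to find.
- **Shape**: expected probe value inside a gene is
  `baseline + amp5·(1−x) + delta·max(0, 2x−1)` — a 5′-biased profile
  (`amp5 = 0.4`) plus a hinged 3′-shift term that is zero on the 5′
  half and reaches `delta` at the 3′ end (`delta = 0.3` in the shifted
  condition). Effects are additive on the log2 scale, matching how the
  difference profiles are computed. The mutant's 5′ loss is modeled by
  reducing `amp5` rather than by a second free function: it is the
  smallest parameterization that reproduces the qualitative
  decrease-5′/increase-3′ difference curve, including its reversal
  when `delta` returns to 0.
- **Noise**: i.i.d. Gaussian per probe, `noise_sd = 0.25` log2 units;
  intergenic probes are `Normal(0, noise_sd)` (enrichment is relative
  to input, so background is 0). The shift and noise magnitudes are
  package defaults chosen to put per-position effects at a few standard
  errors for ~100-gene classes — detectable but not trivial.
- **Companion mark**: a second track whose per-gene baseline is drawn
  with population correlation `mark_rho = 0.58` to the occupancy
  baseline (Gaussian construction `m = ρ·z_b + √(1−ρ²)·z`), the
  gene-level coupling strength typical of co-transcriptional marks.
- **qPCR**: replicate IP/input pairs whose percent input is truth ×
  lognormal noise with a stated CV and unit mean.

What the generator does *not* emulate — and therefore what green tests
do not demonstrate about real arrays: probe-specific affinity and
cross-hybridization, dye and batch effects, spatially correlated noise
along the chromosome, transcript-isoform and UTR-length variation, and
any non-Gaussian heavy tail in probe error. The statistical machinery
is validated on the generative model's terms; claims about a real
dataset still require the usual inspection of that dataset.

## Verification strategy and problem sizes

The test suite checks every numerical path against an independent
route: binning against an exhaustive per-probe loop on 200 random
instances (≤50 genes, ≤2000 probes); the t machinery against the
closed-form t CDF at df = 2; hypergeometric tails against complete draw
enumeration; Welch statistics against the hand-written formulas; and
the geometry against invariances (translation of all coordinates,
mirror-plus-strand-flip of the genome, BED6/GFF3 agreement). Calibration
runs use 400-gene genomes — 50 null seeds for the type-I rate of the
tiered tests (the observed fraction of p ≤ 0.01 cells must sit in the
99% binomial band) and paired shifted/reverted simulations for effect
recovery — and 100 seeds of 2000-gene genomes for correlation recovery,
sizes at which the binomial and Fisher-z bands are tight enough to be
informative while the whole suite stays in the minutes range on one
CPU. Because a reverted (null-3′) condition still tests ~70 coding
positions at p ≤ 0.01, the reversal check requires zero dark-tier
positive calls and caps light-tier positives at the 99.5% binomial
null quantile rather than literal zero — the calibrated reading of
"no significant 3′ gain".

## Known limitations

- The pipeline consumes *already normalized* enrichment values; array
  preprocessing (background correction, within/between-array
  normalization) is upstream and out of scope.
- Quartile boundaries are hard splits; genes near a boundary belong
  entirely to one class.
- The 50-bin scaled coordinate conflates genes of different lengths;
  at 200 bp tiling most gene × bin cells are empty and per-cell n, not
  the gene count, is the effective sample size (the output reports it).
- `rank_changes` scores are unshrunken means; with few covered bins a
  gene's score is noisy, and the top lists inherit that noise.
- Hypergeometric enrichment treats categories independently and flat;
  no ontology propagation or category overlap correction is attempted.
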