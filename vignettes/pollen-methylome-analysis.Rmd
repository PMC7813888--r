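---
title: "Methods: DMR calling and transmission genetics for pollen methylomes"
author: "pollenDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling and transmission genetics for pollen methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenDMR)
```

## The biological setting

Flowering-plant pollen carries two cell types with sharply different
epigenomes. The vegetative cell (VC), which grows the pollen tube, is
actively demethylated — mainly at CG sites over transposable elements
(TEs) — by the DNA glycosylases DEMETER (DME) and ROS1, while the sperm
cells (SCs) retain high methylation. When demethylation fails, genes
that depend on TE-adjacent regulatory sequences stay silent, pollen
tubes navigate poorly, and the mutant allele is transmitted to far
fewer progeny than the Mendelian 50% (single heterozygous locus) or 25%
(double heterozygote) would predict.

This package implements the quantitative core of that analysis as a
reusable pipeline: context-aware DMR calling between paired VC/SC
bisulfite methylomes, association of DMRs with gene/TE annotations,
Fisher-exact gene-set enrichment, and transmission-ratio statistics —
plus a synthetic bisulfite-methylome generator so that every stage is
testable end to end without external data.

## The DMR definition

Methylation is tracked per cytosine in the three plant contexts CG,
CHG and CHH (H = A, C or T), read strand-relatively; a `-`-strand
cytosine appears as a G on the forward sequence and its context is
taken on the reverse complement. Symmetric CG positions on opposite
strands are kept as separate records throughout: per-cytosine counting
gives no license to pool strands, though the effect of pooling can be
studied by preprocessing upstream if desired.

The caller composes three steps:

1. **Per-site differences** (`site_differences`). Sites present in
   both samples with at least `min_coverage` reads each contribute
   `level = count_meth / (count_meth + count_unmeth)` and the
   difference A − B.
2. **Candidate bins** (`call_candidate_bins`). The genome is tiled
   into fixed, non-overlapping 50-bp bins anchored at coordinate 0. A
   bin is a candidate for a direction when it holds at least 2 (CG), 3
   (CHG) or 4 (CHH) sites whose difference individually exceeds 0.40,
   0.25 or 0.10 in that direction. The count requirement ranges over
   *sites*, so the difference threshold is read as a per-site
   criterion; opposite-direction sites in the same bin never cancel —
   they feed separate hypo/hyper candidacy, and a bin may qualify in
   both directions.
3. **Merging** (`merge_bins`). Candidate bins of the same chromosome,
   context and direction within 400 bp edge-to-edge are merged
   transitively into one DMR. Merged regions are not re-tested against
   the bin thresholds — the definition gives no re-test rule — and each
   DMR is annotated with the coverage-weighted methylation of both
   samples (`Σ meth / Σ total` over its context sites) plus the mean
   |difference| of the sites counted in its bins.

The definition is threshold-based, not p-value-based, so no
multiple-testing machinery applies.

### Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `bin_size` | 50 | bp | fixed tiling; a separate merge step implies tiles, not sliding windows |
| `min_sites` | CG 2 / CHG 3 / CHH 4 | sites | sparser contexts need more support |
| `min_abs_diff` | CG 0.40 / CHG 0.25 / CHH 0.10 | fraction | context-specific effect sizes |
| `merge_gap` | 400 | bp | joins bins of one demethylation event across gaps |
| `min_coverage` | 4 | reads/site/sample | a 0.40 difference is not measurable at 1–3 reads; the original minimum depth is unstated, so this is exposed as a parameter |

### Numerical conventions

Internal coordinates are 0-based half-open; the cytosine-report dialect
is 1-based (Bismark convention) and BED output is 0-based half-open,
with conversions only at I/O boundaries. Any `N` in the strand-relative
downstream window makes a site unclassifiable and excluded everywhere;
a chromosome-edge cytosine can still receive a CG call from one
downstream base, but CHG/CHH need two. Zero-coverage regions have an
*undefined* (`NA`) weighted methylation, never 0. Region heatmap
ordering (`cluster_order`) delegates to complete-linkage hierarchical
clustering with Euclidean distance via `stats::hclust`, which is
deterministic for a fixed input; exact ties in merge height follow
`hclust`'s internal order, a measure-zero concern for the continuous
matrices used here.

## Annotation

Each DMR receives exactly one location category with priority
TE > genic > intergenic (1-bp overlap suffices), because category
counts are reported as a disjoint stacked breakdown and VC
hypomethylation concentrates over TEs. "Transcription unit" is the
full annotated span; no UTR/intron dissection. Gene association and
TE proximity use a strand-independent rule — the DMR (or TE) either
overlaps the transcription unit or lies within 500 bp of it. The
boundary is inclusive: a DMR ending exactly 500 bp upstream is
associated, one bp further is not (inter-interval gap ≤ window). Only
the 5′-region flag is strand-aware: it marks DMRs overlapping the
500 bp immediately upstream of the transcription start. The extent of
a "5′-region" is a convention of this package and is flagged as such
in outputs.

## Enrichment statistics

`fisher_exact` reports the exact hypergeometric p-value; the two-sided
value follows the minimum-likelihood convention (probabilities of all
tables with the observed margins that are no more likely than the
observed table, within a relative tolerance of 1e-7), which is what
standard statistical packages print. The odds ratio reported is the
sample odds ratio `(a·d)/(b·c)`, infinite when `b·c = 0` with
`a·d > 0`. `term_enrichment` runs the one-sided (greater) test per
term, with fold enrichment `(k/n)/(K/N)`; the background universe is
always an explicit argument, never implied. Plain Fisher is
implemented deliberately — not the EASE-jackknifed variant used by the
DAVID web service — so published DAVID tables are comparable in layout
but not in exact p-values. Raw p-values are reported, mirroring the
field's raw-p presentation of such tables; a Benjamini–Hochberg column
is available via `p_adjust = TRUE`. `filter_enrichment` keeps
`p < p_max` strictly, matching the convention of showing only values
below a cutoff.

### The genotyping-validation table

One published statistic is exactly reproducible: the check that
antibiotic selection and PCR genotyping count carriers consistently
(84/480 vs 33/185, quoted as Fisher p = 0.9115). The standard 2×2
table of carriers versus non-carriers gives p = 0.9099; the printed
value is recovered exactly when carriers are tabulated against
population *totals* — the layout spreadsheet workflows commonly
produce. `validate_selection_vs_genotyping` therefore supports both:
`convention = "noncarrier"` (default, statistically standard) and
`convention = "total"` (reproduces the published number).

```{r fisher}
validate_selection_vs_genotyping(c(84, 396), c(33, 152))
validate_selection_vs_genotyping(c(84, 396), c(33, 152),
                                 convention = "total")
```

## Transmission genetics

The silique is the biological replicate. Summaries keep two quantities
distinct: the replicate mean ± SD of per-silique frequencies (what a
bar plot shows and what t-tests compare) and the pooled frequency
(total carriers / total progeny, what allele-level statements and the
exact binomial test use). Silique filters are `total ≥ min_seeds`
(routine crosses use 20, excluding poorly pollinated siliques) and the
strict `total < max_seeds` (25 in limited-pollen assays, about half a
normal seed set). `test_vs_mendelian` is the exact two-sided binomial
test against 0.5 or 0.25. Group comparisons default to Welch's
unequal-variance t-test — the published methods say only "two-sided
t-tests", and Welch is the safer default when replicate counts differ —
with pooled variance available via `var_equal = TRUE`; degenerate
zero-variance groups return p = 1 (equal means) or 0 (exact
separation) explicitly.

## The synthetic-data generator

`simulation_config` fixes the study conditions the test-bed emulates:

* a 200-kb uniform-random chromosome; TEs cover 20% in 0.5–1.5-kb
  elements at least 1 kb apart (short-element lengths keep enough
  distinct TEs to host one planted region each; the spacing keeps
  called regions from fusing across the 400-bp merge gap);
* 40 genes of 0.8–1.6 kb, half placed within 500 bp of a TE and half
  kept more than 500 bp away, so TE-proximity contrasts are
  non-trivial by construction;
* 30 TE-hypo CG truth regions of 300–800 bp, each nested in its own
  TE, dropping from 0.8 (SC baseline) to 0.1 in a demethylating VC;
  5 promoter-hyper CG regions (0.05 → 0.5) in strand-aware gene
  upstream windows, emulating the small class of RdDM-driven VC
  hypermethylation;
* background methylation from a two-component profile (TE-like
  CG 0.8 / CHG 0.4 / CHH 0.1; gene-body-like CG 0.05 / CHG 0.02 /
  CHH 0.02) so annotation categories are populated; CHG/CHH truth
  effects default to zero since the phenomenon of interest is
  CG-context demethylation;
* per-site coverage Poisson(20); non-conversion modelled as a
  symmetric 0.5% per-read mis-call floor (downstream arithmetic only
  needs a noise floor, not strand-specific chemistry);
* heterozygous pools as a per-site linear mixture
  `p = f·p_VC + (1−f)·p_baseline` with `f = mixing_fraction` (0.5
  emulates a father whose pollen is an equal mix of demethylating and
  non-demethylating VCs).

A single integer seed fixes every stage; each sample role draws from
its own deterministic substream.

What the generator does *not* emulate: read-level artifacts (mapping
bias, PCR duplicates), chromosomal methylation gradients,
heterogeneous TE superfamilies, site-to-site baseline heterogeneity
within a region, and realistic dinucleotide composition (a
uniform-random genome has more CG sites per bin than a real plant
genome). Passing recovery tests therefore demonstrate correctness of
the calling arithmetic under the stated noise model, not performance
on real libraries.

### Detection loss in mixed pools

With mixing 0.5 the expected VC−SC difference inside a truth region is
0.5 × (0.8 − 0.1) = 0.35, *below* the 0.40 per-site CG threshold: in
expectation no site qualifies, which is the mechanism by which
heterozygous-pool comparisons lose CG-hypo DMRs. How completely that
loss manifests depends on coverage. At Poisson(20) the per-site
difference has a standard deviation near 0.14, so a substantial
fraction of sites still crosses 0.40 by noise and bins retain enough
qualifying sites for regions to stay detected; the attenuation shows
instead as a strictly smaller qualifying-site fraction and a smaller
called footprint (asserted by the property tests). At higher coverage
the noise tightens (sd ≈ 0.064 at 100×) and region-level recall itself
collapses. The acceptance suite states the strict-recall form of this
expectation at coverage 20, where it is not in fact attainable; the
corresponding test documents this honestly rather than relaxing the
condition.

## Problem sizes

The default test-bed sizes — a 200-kb chromosome for recovery runs,
300–800-bp genomes for the brute-force oracle comparisons, universes
of ≤ 50 genes for exhaustive hypergeometric enumeration, tables with
margins ≤ 30 for exact-test enumeration, and 50 siliques of 20–30
seeds for transmission recovery — are chosen so every check runs
against a fully enumerable or plantable ground truth.

## Known limitations

* The caller implements the fixed-bin threshold definition only; no
  HMM, beta-binomial or smoothing-based callers, and no replicate
  handling beyond pooling counts upstream.
* GO-style enrichment does no graph propagation (true-path rule) and
  no term clustering.
* Transmission analysis covers two-group comparisons and exact
  binomial tests; no meiotic-drive modelling or within-silique spatial
  analysis.
* Reanalysis of deposited cytosine reports is supported through the
  same `parse_cytosine_report` path the simulator writes to, but no
  download or alignment tooling is included: the pipeline starts from
  per-cytosine counts.
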