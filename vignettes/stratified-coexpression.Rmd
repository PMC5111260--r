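---
title: "Stage-resolved co-expression connectedness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved co-expression connectedness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratanet)
```

## The question the method answers

Given a set of query genes — typically genes differentially expressed
between patient-derived and control neurons — are those genes unusually
*co-expressed* with one another in particular brain regions and at particular
developmental periods?  High mutual co-expression within a region/stage
stratum suggests the query set participates in a coordinated transcriptional
program active there, which is biologically informative when the query set
derives from a developmental disorder such as the 22q11.2 deletion syndrome.

The method works on a developmental brain transcriptome compendium laid out
as a gene-by-sample expression matrix (FPKM-like units) with per-sample
tissue codes and ages.  Samples are partitioned into 16 strata: four
super-regions — frontal cortex (FC), subcortical (SC), sensory-motor (SM),
temporal-parietal (TP), each aggregating the standard tissue codes — crossed
with four developmental stages: embryonic (8–12 post-conception weeks),
fetal (13–26 pcw), early infancy to late childhood (4 months–11 years), and
adolescence to adulthood (13–23 years).  The windows are treated as closed
intervals; samples that fall between windows (27–38 pcw, 12 years, over 23
years) belong to no stage and are dropped with a message rather than snapped
to the nearest window, since their assignment would be arbitrary.

## Networks and the connectedness statistic

Within one stratum, the co-expression network on a gene set is built by
thresholding absolute Pearson correlation: genes $i, j$ are connected when
$|R_{ij}| \ge \tau$, with $\tau = 0.9$ by default.  Both strong positive and
strong negative correlations create edges.  The summary statistic is
**connectedness** — the number of edges — together with per-gene degrees.
`threshold_sweep()` exposes the usual diagnostic for choosing $\tau$: the
goodness of a straight-line fit on log degree versus log frequency, since a
well-chosen threshold tends to produce a heavy-tailed, power-law-like degree
distribution.

Genes with zero variance in a stratum have undefined correlations; these
pairs contribute no edges (rather than erroring mid-pipeline), because a gene
can be locally constant in one stratum while informative in others.  Genes
with zero expression in *every* tissue of *every* stratum are removed from
the query set up front by `drop_zero_expression_genes()`.

Correlations are computed on the expression scale as given.  The raw
FPKM-like scale is the default; a `transform = "log2"` switch applies
$\log_2(x + 1)$ first.  Both conventions are defensible for compendium data
and the choice is exposed rather than hidden because it can move individual
pairs across a hard threshold.

## The expression-rank-matched permutation null

Raw connectedness is not interpretable on its own: highly expressed genes
correlate more reliably than weakly expressed ones, so a query set enriched
for well-expressed genes would look "connected" for reasons that have nothing
to do with biology.  The null model therefore matches on expression rank.
Within each stratum:

1. rank all genes by mean expression across the stratum's tissues
   (rank 1 = highest; ties broken by gene id so the ranking is stable);
2. for each query gene, draw uniformly one non-query gene whose rank lies
   within ±`window` positions (default 5) of the query gene's rank, without
   replacement across query genes; if a window is exhausted by earlier draws
   it is widened one position at a time to the nearest eligible gene, with a
   warning;
3. build the $\tau$-network on the drawn set and record its connectedness;
4. repeat `B` times (default 10,000) and compute the one-tailed (larger)
   empirical p-value with the add-one estimator
   $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$,
   which can never return zero and corresponds to pooling the observed value
   into its own ensemble.

The matched draw excludes all query genes and already-selected genes; ranks
are recomputed per stratum because expression levels differ across strata.
Per-stratum p-values are adjusted across the 16 strata jointly with the
Benjamini–Hochberg step-up (`stats::p.adjust`), and strata with $q < \alpha$
(default 0.05) are flagged.  The per-stratum random streams are forked from
the master seed by a stable hash of the stratum key, so results are
independent of evaluation order.

The inner loop (matched draws plus edge recount) is implemented in C++ via
Rcpp using R's own RNG; `set.seed()` fully determines every result.

## Hubs, cross-stratum consistency, and expansion

`rank_by_connectivity()` ranks genes by their number of connections, either
within one stratum or summed across networks (e.g. the four regions of one
stage — the "stage total"), with deterministic id tie-breaks.
`top_fraction()` takes the top `floor(fraction × n)` genes; with the default
10% a 736-gene query set yields exactly 73 genes (floor is used because
0.1 × 736 = 73.6, and a strict count keeps the selection reproducible).
`rank_correlation_matrix()` correlates the connectivity ranking orders across
strata — Pearson on ranks, i.e. Spearman's $\rho$ with average ranks under
ties — quantifying whether the same genes are hubs in different
regions/stages.  A stratum whose network is empty has no ranking order and
yields `NA` correlations.

`expand_to_nondeg()` widens the view: for every background (non-query) gene
it counts $|R| \ge \tau$ links to the top query genes, ranks the background
genes by that count, and selects either a fixed number (default 300, giving
a 373-gene combined set with 73 top query genes) or a fraction of the genes
with at least one connection.  The fixed count is the default because "top
10% of connectors" depends on how many genes connect at all, which varies
with $\tau$ and data; both rules are available.

## Positional and dosage statistics

For a hemizygous deletion, `deletion_dosage_profile()` computes each gene's
case/control mean-expression ratio and $\log_2$ fold change, summarised by
the median inside the deletion interval (expected near −1, i.e. half dosage)
and among flanking genes (expected near 0).  Interval membership uses any
overlap of the gene body with the interval in 0-based half-open coordinates.

`region_counts()` + `chi2_2x2()` formalise the positional claim: on the
deletion's chromosome, genes are cross-classified by interval membership and
by a pluggable significance rule (nominal `p` or FDR `q` below a level — the
rule is pluggable because different parts of such analyses legitimately mix
the two), and a 1-df Pearson chi-squared test is applied.  The Yates
continuity correction is on by default, matching the convention of standard
statistical environments for 2×2 tables; a zero marginal raises an error
that advises an exact test instead.

`find_interacting_regions()` scans a binned interaction-correlation track
(mean correlation of chromatin-contact profiles with a query locus) for
maximal runs of adjacent bins strictly above the cutoff (default 0.4; a bin
at exactly 0.4 does not pass), and `interaction_enrichment()` tests each
resulting region for enrichment of significant genes against the rest of its
chromosome — the chromosome, not the genome, is the universe, matching how
positional enrichment is usually displayed along the interacting chromosome.

## Batch step

`upgma_batches()` reproduces the usual expression-QC step of clustering
samples by UPGMA (average linkage) on the correlation distance
$1 - R$ and cutting the tree into two batches; samples are processed in
lexicographic id order so the result is independent of column order.
`location_scale_adjust()` is deliberately simple plumbing: per gene it
standardises within batch and restores the pooled mean and standard
deviation, which removes additive and multiplicative batch offsets while
preserving each gene's pooled mean exactly.  It is a location/scale
adjustment, not an empirical-Bayes batch model; genes with zero within-batch
variance are recentred only.

## What the simulator emulates — and what it does not

`simulate_grouped_expression()` generates the compendium at the canonical
layout (16 strata, 398 specimens with the standard per-stratum counts,
exposed by `brainspan_strata_counts()`), with ages drawn inside the correct
stage windows so the stratifier is exercised end to end.

* **Baselines.**  Gene baselines are log-normal (`meanlog` 1, `sdlog` 1),
  reproducing the heavy right tail of FPKM marginals.  Within a stratum each
  gene fluctuates across tissues by an independent log-normal factor with
  log-sd 0.5 — a typical between-specimen coefficient of variation for bulk
  brain tissue expression.
* **Planted modules.**  A module replaces the independent fluctuation of its
  genes, in its active strata, by `loading × factor + noise` on the log
  scale, one standard-normal factor per tissue.  The within-module log-scale
  correlation is `loading² / (loading² + noise²)`;
  `module_noise_for_r()` inverts this.  On the raw scale the correlation is
  slightly attenuated by the exponential, which is why tests targeting
  $|R| \approx 0.95$ use a modest loading (0.5) where the transform is
  near-linear.  Query-gene baselines are drawn from the same distribution as
  every other gene, so rank-matching is meaningful, and the hub gene of a
  module is the member with the largest loading.
* **Deletion study.**  Non-overlapping genes are laid across the deletion
  interval (47 genes by default) and the rest of the chromosome (311), with
  the hemizygous effect applied as a −1 shift in $\log_2$ space with small
  per-gene jitter (sd 0.05) — a shift, not a zeroing, because the loss is
  hemizygous.  Case/control matrices (10 vs 9 specimens, the scale of a
  small iPSC cohort) are generated consistently with residual log-sd 0.1,
  reflecting batch-corrected values; background genes carry exactly zero
  planted effect and uniform p-values.
* **Interaction track.**  Background bins fluctuate near 0.1 and one planted
  run of bins sits at 0.5; `simulate_positional_degs()` plants significance
  five times denser inside a chosen region for enrichment tests.

Not emulated: read-level sequencing noise, library-size effects, isoform
structure, spatial correlation of expression along chromosomes, realistic
gene-gene correlation beyond the planted modules, and batch structure beyond
a two-batch location/scale shift.  Passing tests therefore demonstrate that
the *algorithms* behave correctly under controlled structure — calibration
under the null, power against planted signal, exact arithmetic — not that
any particular biological dataset will show the same effect sizes.

## Numerical choices and degenerate inputs

* Empirical p-values use the add-one estimator; `p = 1` when the observed
  count is 0 (every null count is ≥ 0).
* Threshold comparisons: network edges use `|R| ≥ τ`; the interaction-track
  cutoff is strict `>`; the mean-expression filter is `≥` by default with a
  `strict` flag, since both conventions appear in practice.
* Ties: expression ranks, connectivity rankings and agglomeration order all
  break ties deterministically (gene/sample id), so every result is
  reproducible across platforms.
* Degenerate inputs: strata with fewer than 3 tissues are rejected
  (correlation is meaningless below that); zero-variance genes yield `NA`
  correlations and no edges; empty networks yield `NA` rank correlations; a
  2×2 table with a zero marginal is rejected with advice to use an exact
  test.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic data
at deliberately modest scale: compendia of 200–1000 genes over the canonical
398-specimen layout, `B = 200–500` null iterations, 200 replicate datasets
for calibration and 50 seeds for power, which together complete in a few
minutes on one CPU while exercising every code path at the study's stratum
sizes.  The defaults wired into the functions (`τ = 0.9`, `B = 10000`,
window 5, top fraction 0.1, 300 background genes, `α = 0.05`, FPKM cutoff 1,
interaction cutoff 0.4) are the constants a full-scale analysis would use.

## Known limitations

* The rank-matched null controls for expression level only; other gene
  properties that affect correlation detectability (transcript length,
  GC content, tissue specificity) are not matched.
* Connectedness is a global count; it does not distinguish one dense clique
  from many small components.
* In the synthetic end-to-end pipeline the compendium query set and the
  deletion study use separate simulated gene universes, so the pipeline
  demonstrates the plumbing of both arms rather than a shared-gene analysis.
* The location/scale adjustment deliberately ignores covariate structure
  beyond the two batches.
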