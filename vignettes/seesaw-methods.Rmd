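---
title: "Methods: inverse differential-expression analysis for two-stress designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse differential-expression analysis for two-stress designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seesawr)
```

## The problem

*C. elegans* larvae that transit the stress-induced dauer stage carry a
transcriptional memory of which stress sent them there. Comparing
postdauer to control adults (PD/CON) under two dauer triggers —
pheromone (Phe) and starvation (Stv) — yields two per-gene
differential-expression contrasts. A **seesaw gene** responds in
*opposite* directions under the two triggers: up in PD_Phe/CON_Phe and
down in PD_Stv/CON_Stv, or the reverse. seesawr implements the
downstream statistics such a design needs once the per-contrast DE
tables exist: seesaw calling, randomization nulls for set overlap,
chromosome-scale spatial statistics, operon summaries, and library QC.
The package consumes DE tables; it never refits the DE model itself.

## Seesaw calling

For each gene we observe `(log2fc_phe, log2fc_stv)` with per-contrast
Benjamini–Hochberg q-values. The plane partitions into quadrants:
Q1 (Phe up, Stv down), Q2 (down, down), Q3 (down, up), Q4 (up, up);
a coordinate exactly zero is labelled BOUNDARY and excluded from
quadrant tallies — the conservative choice for a measure-zero event
that real estimates occasionally produce through pipeline rounding.

* **Significant seesaw** (`call_significant_seesaw`): q < `alpha`
  (default 0.05) in *both* contrasts with opposite signs. The cutoff is
  applied per contrast; no combined cross-condition test is attempted,
  matching the convention of thresholding each contrast at FDR < 5%.
  A gene significant in both contrasts with the *same* sign is reported
  separately (`shared_up` / `shared_down`). A `loose = TRUE` variant
  requires significance in only one contrast (the inverse sign pattern
  still in both); it is not the default because single-contrast
  significance plus an unreplicated direction is a materially weaker
  claim, but it is useful for sensitivity analyses of the cutoff rule.
* **Trend seesaw** (`trend_seesaw`): an inverse change of at least
  `min_fold` (default 2, i.e. |log2fc| ≥ 1) in both contrasts,
  significance ignored. The threshold is inclusive: "at least 2-fold"
  reads as ≥.
* Reported percentages use `percentage_report`, which rounds half away
  from zero — the rounding that reproduces printed figures such as
  249/441 → 56% and 12,454/18,570 → 67.1%.

`mutant_disruption_classify` compares a mutant's two contrasts against
a known wild-type seesaw orientation with a fixed precedence: mutant
significant in both conditions with opposite signs → retained (same
orientation) or inverted; significant with equal signs → follows the
wild-type Phe or Stv direction; anything else → loss of significance.

## Overlap enrichment by randomization

The expected overlap of two DE gene sets is estimated by Monte Carlo:
each replicate draws two sets of the observed sizes uniformly without
replacement from the gene universe and records their intersection
(`mc_overlap_null`, default 10,000 replicates). Both sets are re-drawn
every replicate. The intersection of two independent uniform subsets is
exactly hypergeometric, so `hypergeometric_expected` (mean `n1*n2/N`)
is an analytic oracle against which the simulation is continuously
tested. Fold enrichment is observed/null-mean; the empirical p is the
fraction of replicates at or above the observed overlap, printed as
"< 1/S" when no replicate reaches it (no +1 correction, so a
zero-exceedance run reports the resolution of the simulation rather
than a pseudo-value).

The universe defaults to the genes quantified in both DE tables and is
deliberately exposed as a parameter: published fold enrichments of this
kind are sensitive to the universe choice, and reported values cannot
generally be reproduced without knowing it exactly. Two-set Fisher
tests (`fisher_two_tailed`) are computed by direct hypergeometric
enumeration with the standard two-sided rule (all tables with point
probability ≤ observed, relative tolerance 1e-7).

## Spatial statistics

**Per-chromosome bias** (`chrom_bias_chi2`): for each chromosome, a
2×2 table of (class / non-class) × (this chromosome / remaining
chromosomes), with Yates continuity correction clamped at zero:
χ² = Σ (max(|O−E|−0.5, 0))²/E, df = 1. A one-sample variant testing
the class's chromosome counts against gene-count-proportional
expectation is available via `method = "proportional"`; the two
formulations answer subtly different questions and both appear in the
literature, so both are implemented with the 2×2 form as default.

**Sliding windows** (`sliding_window_enrichment`): 2.5 Mb windows
advancing by 500 kb from position 0; terminal windows are truncated and
flagged. A gene belongs to a window iff its midpoint lies in
[start, end) — midpoint assignment avoids double counting beyond the
intended window overlap. Enrichment is the window's class fraction over
the genome-wide class fraction; windows with fewer than `min_genes`
(default 10) genes are NA rather than yielding unstable ratios.

**Co-localization clustering** (`glc_cluster`): within a chromosome, a
cluster is a maximal run of attribute-flagged genes in which
consecutive attribute genes are separated by at most `max_gap`
non-attribute genes, holding at least `min_size` (default 3) attribute
genes; gap genes are not members. Significance comes from
`cluster_null`: the attribute labels are permuted uniformly over gene
positions (gene order and chromosome sizes fixed) and both the cluster
count and the clustered-gene count are re-measured per replicate.

The default `max_gap` is 1. At attribute densities near 0.2 — the
regime of germline target sets of ~4,000 genes in a ~19,000-gene
genome — a gap tolerance of 2 makes the *permuted* null itself
cluster more than half of all flags, so that genuinely clustered sets
can show *fewer* (larger) clusters than random even while clustering
far more genes. With `max_gap = 1` both statistics of a clustered set
exceed their nulls and the cluster-size spectrum stays dominated by
3–10-gene clusters, which is the qualitative structure reported for
real germline-target sets. Both parameters remain configurable.

**Operons** (`operon_membership`, `operon_quadrant_classify`): a gene
set's operon membership count/percentage, and per-operon quadrant
labels computed on the mean member log2 fold change per condition
(an operon whose mean is exactly zero in either condition is BOUNDARY;
operons with no quantified members are skipped and counted).

## Expression QC

`replicate_pearson` correlates two libraries on the log2(count+1)
scale by default; raw-scale correlation is available because
correlations on untransformed counts are dominated by the few
highest-expressed genes, and both conventions appear in published QC
panels. The p-value offers df = n−1 ("legacy" mode, as sometimes
printed) and the conventional df = n−2.

`pc_significance` eigen-decomposes the correlation matrix *among
samples* (genes as observations, log2(count+1) by default), so
eigenvalues sum to the number of libraries and the Kaiser rule
(λ > 1) is meaningful. The broken-stick expectation is
b_k = (1/p)·Σ_{i=k..p} 1/i, which sums to 1; a component is retained
when its variance share exceeds b_k.

`germline_enrichment_classify` labels a gene germline-enriched when
its ablated/wild-type FPKM ratio (with pseudocount 0.1) falls at or
below 0.5. Published analyses state only that germline-enriched genes
are "substantially decreased" after germline ablation; the 0.5/0.1
pair is an explicit, monotone surrogate for that judgement, and both
knobs are exposed. Genes whose wild-type FPKM does not exceed the
pseudocount are `undetermined` rather than forced into either class.

## The synthetic study

`simulate_study(generator_config())` generates the full artifact
bundle with a per-gene truth table. The defaults *are* the study
conditions the analyses assume:

* **Genome**: six chromosomes (I, II, III, IV, V, X) of 15.1, 15.3,
  13.8, 17.5, 20.9, 17.7 Mb; 18,570 genes as non-overlapping intervals
  with lengths uniform in [0.5, 5] kb. (A mean gene length above ~5 kb
  cannot pack 18,570 non-overlapping genes into a ~100 Mb genome;
  0.5–5 kb both fits and matches real nematode gene lengths.)
* **Response classes**: 500 significant seesaw genes (250 per
  orientation), 1% concordant responders, the rest null. Planted
  |log2FC| ~ N(1.5, 0.2) truncated at zero; the p-value model is the
  normal tail p = 2Φ(−|log2fc|/0.3). The fold change itself carries no
  added noise — the planted sign structure is exact — and a BH
  threshold analysis at 500 signals among 18,570 genes puts the
  per-contrast miss probability near Φ(−2.7), i.e. a both-contrast
  recall around 0.99 by design, before any test was run.
* **Null genes** get bivariate-normal fold-change pairs with sd 0.3
  (so their p-values are exactly uniform) and correlation
  ρ = −sin(π(f − ½)) with f = 0.671: by the bivariate-normal orthant
  identity this makes the expected Q1+Q3 share exactly the configured
  genome-wide inverse-trend fraction.
* **Placement**: planted seesaw classes choose interval slots with
  weight Beta(a, a) at the slot's relative midpoint, a = 1/(1−c),
  c = 0.9 by default, on chromosomes weighted per class (up_down
  toward I and III, down_up toward II, V, X). Non-overlap is
  guaranteed by construction: intervals are laid out first, classes
  are then assigned to slots, so central bias never causes collisions.
* **Attribute set**: 4,191/18,570 of genes; 75% planted in runs of
  3–8 (geometric weights, internal gaps ≤ 1) and 25% scattered singly,
  with chromosome weights giving ~1.4× density on I/III and ~0.65× on
  V/X. These values were calibrated to the published qualitative
  cluster structure — roughly three quarters of targets clustered,
  mean cluster size ~6, size spectrum dominated by 3–10, and both
  clustering statistics above their randomization nulls.
* **Operons**: 15% of genes in runs of 2–4 adjacent genes forced onto
  a shared strand. **Counts**: negative binomial (dispersion 0.05,
  Poisson at 0) around shared log-normal means, two replicates per
  strain; germline-flagged genes are scaled by 0.2 in the ablated-like
  strain.
* **Seeds**: one master seed fans out to fixed per-stage child seeds
  via `stage_seed()` (affine map modulo 2³¹−1), so any stage is
  reproducible in isolation and adding a stage never shifts another
  stage's stream.

What the generator does *not* emulate: per-gene length–expression
coupling, GC or mappability artifacts, batch structure, partially
overlapping or nested gene models, and any dependence between operon
membership and expression class. Tests passing on this fixture
therefore demonstrate correctness of the statistics under their own
assumptions, not robustness to those real-data complications.

## Numerical and degenerate-input choices

* BH q-values clip at 1 and preserve input order; empty input gives
  empty output.
* Overlap folds with a zero null mean (empty comparison set) are NaN,
  flagged, never an error.
* Sliding windows never divide by zero: sparse windows are NA.
* Chromosomes whose expected class count is zero are flagged
  untestable in the bias test rather than contributing Inf.
* All randomization p-values use the ≥ tail with ties counted, making
  them conservative (super-uniform) under their own nulls; this is
  verified by calibration tests.

## Problem sizes used in the shipped tests

The test suite exercises the full 18,570-gene fixture for the
end-to-end recovery checks and smaller fixtures (400–10,000 genes) for
structural properties; randomization nulls run at S = 200–10,000
depending on what the check needs to resolve. These sizes were chosen
so the whole suite completes in a few minutes while keeping every
Monte Carlo tolerance at least three standard errors wide.
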