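---
title: "Methods: discovering lineage-restricted transcription factors with hemaTFnet"
author: "hemaTFnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering lineage-restricted transcription factors with hemaTFnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hemaTFnet nominates transcription factors (TFs) that are restricted to, and
potentially instructive for, individual hematopoietic lineages (B, T, NK,
innate lymphoid and dendritic cells), starting from bulk RNA-seq counts of
sorted populations. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one defensible choice
existed.

## Overview of the workflow

1. **Filtering and normalization.** Genes are kept when they have a count of
   at least `min_count` (default 10) in *strictly more than* a fraction
   `sample_fraction` (default 0.70) of samples and a total of at least
   `min_total` (default 100). Expression is normalized to log2 counts per
   million (log2 CPM) with TMM library-size rescaling and a flat prior count
   of 2.
2. **Differential expression vs. the stem compartment.** Every
   differentiated group is contrasted against the stem group on the log2 CPM
   scale. Significance requires FDR ≤ 0.05 (Benjamini–Hochberg) and an
   absolute log2 fold change of at least 0.585 for TFs or 1 for all other
   genes — TFs act catalytically, so a ~1.5-fold change is already
   meaningful, while other genes must double.
3. **Lineage specificity.** For gene *g* and group *k*,
   *S(g,k) = x̄(g,k) / mean over groups of x̄(g,·)*, where x̄ is the mean of
   sample means, so groups weigh equally under unbalanced replication. The
   scores of a gene average to 1 over groups; a gene expressed in exactly
   one of *K* groups scores *K* there and 0 elsewhere.
4. **Signed co-expression network.** Adjacency
   *a(i,j) = ((1 + cor(i,j))/2)^β* with Pearson correlation (β = 16 for the
   all-lineage run, 12 for the smaller DC-only run), topological overlap
   (TOM) similarity, module detection on 1 − TOM, module eigengenes,
   module–trait correlation against one-hot group indicators, module
   membership (MM) and gene significance (GS).
5. **Regulatory-network integration.** Per-group DEG lists are tested
   against a ChIP-derived TF→target gene-set library with a one-sided
   Fisher exact test (kept at raw p ≤ 0.05 when the TF itself is expressed
   in the group, mean log2 CPM ≥ 1); curated regulator→target edges are
   looked up for expressed TFs; both are merged with the TF-centric
   co-expression edges, deduplicated, projected onto TFs with full-network
   degree as the centrality scale, and annotated with the mean promoter
   accessibility (OCR at TSS) of each TF's interactors.
6. **Prioritization.** Per group, the module(s) most correlated with the
   group contribute their TFs with MM ≥ 0.5; each candidate row collects
   expression, fold change, specificity, degree, evidence sources and
   interactor accessibility, and unknown candidates are ordered by an
   equal-weight rank-sum over those criteria.

## The DE test is a documented stand-in

The canonical tool for step 2 is a count-model test (quasi-likelihood or
exact). hemaTFnet deliberately implements a Welch two-sample t-test on
log2 CPM instead: it is transparent, dependency-light, well calibrated on
the replicate numbers this workflow targets (the test suite checks the
type-I rate on a 1,000-gene null simulation), and the thresholds and flags —
which is what downstream stages consume — follow the workflow conventions
exactly. It is *not* numerically equivalent to edgeR-style inference, and at
very low replication (n = 2–3 per group) a moderated count model would be
more powerful.

## Module detection: a deterministic static cut

Dynamic hybrid tree cutting is deliberately out of scope; hemaTFnet uses a
deterministic variant with the same user-facing knobs:

* Average-linkage clustering on 1 − TOM.
* **Largest-gap cut.** Genuine co-expression modules finish merging at
  dissimilarities far below the heights at which unclustered genes
  aggregate, so the sorted merge heights are effectively bimodal. The tree
  is cut at the midpoint of the largest gap in the sorted heights, searched
  among heights at or below a quantile indexed by `deep_split`
  (0..3 → 0.95, 0.92, 0.90, 0.88). A plain quantile cut was rejected: on
  signed-TOM dendrograms nearly all merge heights crowd toward 1, so any
  fixed high quantile lands inside the background-aggregation regime and
  fuses modules with noise genes. Capping the gap search lower (larger
  `deep_split`) can only move the cut down, preserving the "deeper split ⇒
  at least as many raw clusters" semantics.
* **Small-cluster absorption with a significance gate.** Clusters below
  `min_module_size` (default 50) are absorbed into the retained module whose
  eigengene they correlate with best, provided the correlation clears both a
  flat floor (`merge_cor_min` = 0.3) and two-sided significance at
  `merge_alpha` = 0.01 for the available sample count. The flat floor alone
  is unsafe at small n: with 30 samples, r = 0.3 is p ≈ 0.11, and hundreds
  of unclustered genes would be absorbed on correlations indistinguishable
  from noise. Remaining clusters are labeled 0 (unassigned). Module ids are
  assigned by decreasing size.

Eigengenes are the first principal component of the module's standardized
expression, sign-oriented so the correlation with the module's average
profile is positive — without that convention MM signs would be arbitrary.

## Edge extraction and the two thresholds

Exported edge weights are TOM values, not raw correlations: the
co-expression export convention reads "correlation" thresholds against the
exported weight. The general network keeps pairs with TOM strictly above
0.01; the TF-centric network keeps TF–gene pairs with TOM ≥ 0.02. A TF's
co-expression degree is its incident-edge count in the TF-centric network;
the candidate table also reports the merged-network degree (`degree`, the
centrality scale of the TF-only view) alongside `degree_wgcna`, because the
two answer different questions (overall evidence vs. co-expression hubness).

## Network merge conventions

Co-expression edges are undirected (stored with lexicographically ordered
endpoints); database edges are directed. Identical (from, to) keys collapse
to one edge with the union of source tags; a directed pair whose unordered
endpoints match an existing undirected co-expression edge is folded into it
rather than inventing a direction. The merge is invariant to input order,
and every edge carries at least one of the tags wgcna, chea, regnet.

## Promoter accessibility

`aggregate_ocr_at_tss()` averages the scores of a group's peaks overlapping
the symmetric window `[tss − w, tss + w)` (default w = 1000 bp, the
conventional promoter-proximal window; BED intervals 0-based half-open, TSS
positions 1-based, strand ignored because no strand rule is defensible
without annotation of regulatory direction). The mean — not the sum — keeps
genes with different peak counts comparable. Interactors absent from the
accessibility table contribute 0 to a TF's interactor-OCR mean: an
unobserved promoter is evidence of closed chromatin in this data model, not
missingness. Input peak scores are assumed already comparable across cell
types; no cross-type renormalization is applied.

## Specificity scale and group universe

Specificity is computed on log2 CPM by default (`specificity_scale`
exposes plain CPM) because candidate tables report expression on that scale;
the score itself is scale-covariant only through the ratio, and both choices
are defensible. The group universe is an explicit parameter: scores are
relative to the groups included, so a DC-subset analysis over
{DC4, DC8, pDC} yields different values than the all-lineage universe.

## Ranking

The workflow lists expression, fold change, specificity and centrality as
prioritization criteria without a combination rule. hemaTFnet uses an
equal-weight rank-sum (six criteria: expression in group, log2FC,
specificity, merged degree, number of evidence sources, interactor OCR),
which is scale-free — invariant to monotone transformations of any single
criterion — and transparent. Weights are a config vector for users who want
to emphasize, e.g., centrality. Ties break lexicographically by TF symbol,
and TFs with reported function (a curated input list) are flagged `known`
and left unranked rather than dropped.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a desk-scaled sorted-population compendium:
6 groups (Stem, B, T, NK, ILC, DC) × 8 replicates, 600 genes with 60 TFs,
three planted modules of 60 genes driven by B, T and NK, one shared
standard-normal latent factor per module with weight `latent_strength` = 0.8
on the natural-log scale, a log2 group effect of 3 for group-restricted
genes, gamma-Poisson counts with dispersion 0.04 (biological CV 0.2, typical
of inbred sorted populations), expected library size 5 × 10⁵, 30 planted
targets per TF, database false-positive/negative rates 0.1, and a promoter
accessibility dropout of 0.2 so a fifth of lineage-restricted genes lack an
open promoter in their own lineage — mirroring the empirical observation
that some lineage TFs have closed TSSs. Decoy TFs (TFs outside any module)
receive targets drawn uniformly from all genes, which is the correct null
for the enrichment filter.

The generator does **not** emulate batch effects, transitional
subpopulations within a lineage, read-level noise, mappability artifacts,
correlated module overlap, or the scale of a real compendium (~100 samples,
>10⁴ genes, dozens of populations). Passing recovery tests on these
simulations therefore demonstrates correctness of the machinery under the
stated statistical model, not performance on real compendia; headline
counts from real studies (tens of modules, thousands of network nodes)
depend on full-scale data and live database snapshots and are outside what
the shipped fixtures can reproduce.

Test and acceptance problem sizes (600–1,000 genes, 30–48 samples, 10–50
oracle replicates) were chosen as the smallest sizes at which the planted
structure is unambiguous; they keep the full suite under a minute on a
single CPU.

## Numerical and degenerate-input choices

* All symbol matching happens after one upper-casing normalization at load.
* Readers reject malformed input (duplicate ids, non-integer counts,
  malformed BED lines with their line number) instead of coercing.
* TOM and adjacency are exact closed-form computations; the test suite pins
  them to brute-force oracles at 1e-12.
* Ties are broken lexicographically everywhere (variable-gene ranking,
  candidate ordering, sample dendrogram leaves), making every output
  deterministic for a fixed config; the only randomness source is the
  config seed.
* Degenerate inputs degrade softly: an empty filter result warns, a module
  assignment with no module ≥ `min_module_size` returns all-unassigned, a
  TF without interactors is annotated 0, a group without a positively
  correlated module yields an empty candidate set with a warning.
* A constant gene is an error in adjacency construction (correlation
  undefined) but only a warning (with exclusion) in the scale-free scan.

## Known limitations

* The Welch stand-in loses power below ~4 replicates per group.
* The static cut assumes modules are tight relative to background; weak,
  overlapping modules (latent strength ≲ 0.3) will not produce a clean
  height gap and end up unassigned.
* Enrichment uses raw p ≤ 0.05 per group (the workflow convention), with BH
  FDR reported but not filtered on; across many groups the family-wise
  decoy rate grows accordingly.
* Accessibility integration is promoter-proximal only; distal enhancers are
  out of scope.
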