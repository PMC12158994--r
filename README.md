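# hemaTFnet

Discovery and prioritization of lineage-restricted transcription factors
(TFs) in hematopoiesis from bulk RNA-seq of sorted cell populations.

Blood cell lineages — B, T, NK, innate lymphoid (ILC) and dendritic cells
(DC) — are installed and maintained by TFs whose expression is restricted
to, or strongly enriched in, one lineage. hemaTFnet is for computational
biologists who have gene-level counts for sorted populations (plus,
optionally, promoter accessibility and TF–target resources) and want a
ranked, evidence-annotated list of candidate lineage TFs.

## What it computes

Given a count matrix, a sample sheet grouping samples into lineages, a TF
symbol list, ATAC peak/TSS tables and TF→target interaction tables, the
pipeline:

1. filters genes (count ≥ 10 in > 70% of samples, total ≥ 100) and
   normalizes to log2 CPM (TMM-scaled, prior count 2);
2. tests each lineage against the stem group; significance needs
   FDR ≤ 0.05 and |log2FC| ≥ 0.585 for TFs (≥ 1 for other genes);
3. scores lineage specificity
   `S(g,k) = x̄(g,k) / mean_k x̄(g,k)` (group mean over the mean of all
   group means);
4. builds a **signed** weighted co-expression network
   `a_ij = ((1 + r_ij)/2)^β` (β = 16; 12 for the DC-only re-run), computes
   topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) /
   (min(k_i, k_j) + 1 − a_ij)`, detects modules (minimum size 50, deep
   split 2), eigengenes, module–trait correlations, module membership (MM)
   and gene significance (GS), and extracts edges (TOM > 0.01; TF edges
   ≥ 0.02);
5. integrates three evidence sources into one regulatory network —
   co-expression edges, ChIP-derived TF→target sets (one-sided Fisher
   exact test per TF on each lineage's DEGs, kept at p ≤ 0.05 if the TF is
   expressed in the lineage) and curated regulator→target tables — then
   deduplicates, projects onto TFs with full-network degree as centrality,
   classifies TFs as specific / multi-group / general, and annotates each
   TF with the mean promoter accessibility (OCR at TSS, ±1 kb) of its
   interactors;
6. selects per-lineage candidates (TFs with MM ≥ 0.5 in the lineage's
   best-correlated module(s)), flags TFs with already-reported function
   from a curated list, and ranks the remaining candidates by an
   equal-weight rank-sum over expression, fold change, specificity,
   degree, evidence sources and interactor accessibility.

A seeded synthetic-data generator (`sim_config()`, `generate_counts()`,
`generate_accessibility()`, `generate_tf_target_db()`) produces studies
with planted modules, lineage-restricted TFs, known target sets and
expression-coupled accessibility, so the whole pipeline is testable
offline. See `vignette("hemaTFnet-methods")` for the model, parameter
rationale and limitations.

## Worked example

Run the full pipeline on the default synthetic study (6 lineage groups ×
8 replicates, 600 genes, 3 planted modules driven by B, T and NK):

```r
library(hemaTFnet)
cfg <- pipeline_config(seed = 1L)
out <- run_pipeline(cfg, "demo_out")   # writes demo_out/candidates.tsv
cand <- read.delim(out)
subset(cand, rank <= 2, select = c(group, tf, expression_log2cpm_in_group,
       log2fc_vs_stem, specificity, degree, network_types, rank))
```

```
group  tf     expression_log2cpm_in_group  log2fc_vs_stem  specificity  degree  network_types      rank
B      TF002  11.46                        2.56            1.28         73      chea_RegNet_WGCNA  1
B      TF004  14.87                        2.31            1.21         71      chea_RegNet_WGCNA  2
NK     TF018  15.01                        2.39            1.18         64      chea_RegNet_WGCNA  1
NK     TF017  13.32                        2.38            1.21         65      chea_RegNet_WGCNA  2
T      TF010  9.60                         2.09            1.32         81      chea_RegNet_WGCNA  1
T      TF012  10.17                        1.90            1.30         81      chea_RegNet_WGCNA  2
```

Each row is one candidate TF for one lineage: its mean log2 CPM in that
lineage, log2 fold change against the stem group, lineage-specificity
score (1 = uniform across groups), merged-network degree, which evidence
sources support its edges (here all three: co-expression, ChIP-derived and
curated), and its rank-sum position among the lineage's unknown
candidates. On this simulation the top-ranked TFs are exactly planted
lineage-restricted TFs, each backed by all three sources.

`run_dc_mode(cfg, "demo_out")` re-runs the co-expression stage on the
stem + DC samples with β = 12 (the smaller-cohort setting), writing
`dc_`-prefixed artifacts. A YAML config and a thin CLI are available:
`Rscript inst/scripts/run_pipeline.R --config cfg.yaml --outdir out`
(stages: simulate, preprocess, specificity, wgcna, integrate, prioritize,
full-run, dc-mode).

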