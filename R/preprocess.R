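#' Filter lowly expressed genes
#'
#' A gene is kept iff it has a count of at least `min_count` in strictly
#' more than `sample_fraction` of the samples AND a total count of at
#' least `min_total` across all samples. The sample set is unchanged; the
#' operation is idempotent.
#'
#' @param counts gene x sample integer matrix.
#' @param min_count per-sample count threshold (default 10).
#' @param sample_fraction fraction of samples that must reach `min_count`
#'   (strict inequality; default 0.70).
#' @param min_total minimum row total (default 100).
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 10, sample_fraction = 0.70,
                         min_total = 100) {
  n <- ncol(counts)
  keep <- rowSums(counts >= min_count) > sample_fraction * n &
    rowSums(counts) >= min_total
  if (!any(keep)) warning("no genes survive the expression filter")
  counts[keep, , drop = FALSE]
}

#' Normalize counts to log2 counts-per-million (TMM-scaled)
#'
#' Library sizes are rescaled by trimmed-mean-of-M-values (TMM) factors;
#' values are `log2((count + prior) / (effective_lib_size + 2 * prior) *
#' 1e6)` with a flat prior count (default 2).
#'
#' @param counts gene x sample integer matrix.
#' @param prior_count flat prior added to every count (default 2).
#' @return numeric matrix of log2 CPM values, same dimnames.
#' @export
normalize_log2cpm <- function(counts, prior_count = 2) {
  lib <- colSums(counts)
  if (any(lib == 0))
    abort("all-zero sample(s): %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  tmm <- edgeR::calcNormFactors(counts, method = "TMM")
  eff <- lib * tmm
  log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}

#' Differential expression of one lineage group against the stem group
#'
#' Per-gene Welch two-sample t-test on log2 CPM values with
#' Benjamini-Hochberg FDR. The log2 fold change is the difference of group
#' means on the log2 CPM scale. Significance requires FDR <= `fdr` and
#' |log2FC| >= `lfc_tf` (0.585) for TFs or `lfc_other` (1) for all other
#' genes. This is a documented stand-in for a count-model test: the
#' thresholds and flags follow the workflow's conventions exactly, the
#' test statistic does not reproduce edgeR.
#'
#' @param counts gene x sample counts (already filtered).
#' @param samples sample sheet tibble (sample_id, group, subgroup).
#' @param target_group group to test.
#' @param reference_group baseline group (default "Stem").
#' @param tf_list character vector of TF symbols.
#' @param fdr FDR cutoff for the significance flag (default 0.05).
#' @param lfc_tf,lfc_other absolute log2FC thresholds for TFs / others.
#' @param expr optional precomputed log2 CPM matrix (recomputed if NULL).
#' @return tibble(gene, group, log2fc, pvalue, fdr, is_tf, significant).
#' @export
differential_expression <- function(counts, samples, target_group,
                                    reference_group = "Stem", tf_list,
                                    fdr = 0.05, lfc_tf = 0.585,
                                    lfc_other = 1, expr = NULL) {
  for (g in c(target_group, reference_group)) {
    n <- sum(samples$group == g)
    if (n == 0) abort("group '%s' absent from sample annotation", g)
    if (n < 2) abort("group '%s' has fewer than 2 samples", g)
  }
  if (is.null(expr)) expr <- normalize_log2cpm(counts)
  a <- expr[, samples$sample_id[samples$group == target_group], drop = FALSE]
  b <- expr[, samples$sample_id[samples$group == reference_group], drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    tryCatch(stats::t.test(a[i, ], b[i, ])$p.value,
             error = function(e) if (abs(lfc[i]) < 1e-12) 1 else 0)
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  is_tf <- rownames(expr) %in% tf_list
  thr <- ifelse(is_tf, lfc_tf, lfc_other)
  tibble::tibble(
    gene = rownames(expr),
    group = target_group,
    log2fc = unname(lfc),
    pvalue = p,
    fdr = q,
    is_tf = is_tf,
    significant = q <= fdr & abs(lfc) >= thr
  )
}

#' Top-k most variable genes by log2 CPM variance
#'
#' Ties are broken by lexicographic gene symbol order, so the selection is
#' deterministic.
#'
#' @param expr log2 CPM matrix.
#' @param k number of genes to return (k <= nrow(expr)).
#' @return character vector of k gene symbols, most variable first.
#' @export
top_variable_genes <- function(expr, k) {
  if (k > nrow(expr)) abort("k (%d) exceeds the number of genes (%d)",
                            k, nrow(expr))
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord][seq_len(k)]
}

#' Sample-level PCA on centered gene features
#'
#' @param expr log2 CPM matrix.
#' @param genes optional gene subset (default all rows).
#' @return list with `scores` (samples x PCs) and `variance_share`.
#' @export
sample_pca <- function(expr, genes = rownames(expr)) {
  if (ncol(expr) < 3) abort("PCA needs at least 3 samples")
  x <- t(expr[genes, , drop = FALSE])
  keep <- apply(x, 2, stats::sd) > 0
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  list(scores = p$x, variance_share = p$sdev^2 / sum(p$sdev^2))
}

#' Average-linkage sample clustering on correlation distance
#'
#' Distance is `1 - Pearson(sample, sample)`; samples are ordered by id
#' before clustering so leaf order is deterministic under ties.
#'
#' @param expr log2 CPM matrix.
#' @return an `hclust` object over samples.
#' @export
sample_hclust <- function(expr) {
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(expr))
  stats::hclust(d, method = "average")
}
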