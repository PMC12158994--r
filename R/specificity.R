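#' Lineage-specificity score
#'
#' For each gene and group, specificity is the gene's average expression in
#' the group of interest divided by the mean of its average expression over
#' all groups:
#' \deqn{S(g, k) = \bar{x}_{gk} / \mathrm{mean}_k(\bar{x}_{gk})}
#' Group means are means of sample means (groups weighted equally
#' regardless of replicate count). By construction the scores of a gene
#' average to 1 across groups whenever its grand mean is positive; genes
#' with grand mean 0 get S = 0 in every group. The score is invariant to
#' multiplying all expression values by a positive constant and
#' equivariant under group relabeling.
#'
#' @param expr expression matrix (log2 CPM by default in this pipeline;
#'   values are expected to be nonnegative on the chosen scale).
#' @param samples sample sheet tibble.
#' @param groups group universe to use (default: all groups in `samples`).
#'   The universe matters: specificity is relative to the groups included.
#' @return tibble(gene, group, specificity).
#' @export
specificity_score <- function(expr, samples,
                              groups = sort(unique(samples$group))) {
  for (g in groups) {
    if (!any(samples$group == g)) abort("group '%s' has no samples", g)
  }
  if (any(expr < 0))
    warning("expression matrix contains negative values; ",
            "specificity assumes a nonnegative scale")
  gm <- vapply(groups, function(g) {
    rowMeans(expr[, samples$sample_id[samples$group == g], drop = FALSE])
  }, numeric(nrow(expr)))
  if (!is.matrix(gm))
    gm <- matrix(gm, nrow = 1, dimnames = list(rownames(expr), groups))
  grand <- rowMeans(gm)
  s <- gm / grand
  s[grand == 0, ] <- 0
  tibble::tibble(
    gene = rep(rownames(expr), times = length(groups)),
    group = rep(groups, each = nrow(expr)),
    specificity = as.vector(s)
  )
}
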