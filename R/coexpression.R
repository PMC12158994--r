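# Signed weighted co-expression network analysis: soft-threshold selection,
# signed adjacency, topological overlap, module detection by a deterministic
# static-quantile cut with small-cluster merging, eigengenes, module-trait
# correlation, module membership / gene significance, and edge extraction.
#
# Expression matrices are genes x samples throughout; correlations are
# Pearson (no missing values allowed upstream).

#' Co-expression network parameters
#'
#' @param soft_power soft-thresholding exponent beta (default 16 for the
#'   all-lineage run; 12 is used for the smaller DC-only run).
#' @param min_module_size smallest allowed module (default 50).
#' @param deep_split split aggressiveness in 0..3 (default 2); mapped to a
#'   merge-height quantile by `deep_split_quantiles`.
#' @param edge_weight_threshold TOM weight above which a gene-gene edge is
#'   exported to the general network (strict >, default 0.01).
#' @param tf_edge_threshold TOM weight at or above which a TF-gene edge
#'   enters the TF-centric network (default 0.02).
#' @param deep_split_quantiles quantile of the merge-height distribution at
#'   which the dendrogram is cut, indexed by deep_split 0..3.
#' @param merge_cor_min minimum eigengene correlation for absorbing a
#'   small cluster into a module (default 0.3); below it the genes stay
#'   unassigned (module 0).
#' @param merge_alpha the absorbing correlation must additionally be
#'   significant at this two-sided level (default 0.01), so the merge
#'   floor adapts to the sample size: with few samples a flat correlation
#'   floor would absorb genes whose correlation is indistinguishable from
#'   noise.
#' @return a validated `coexpression_params` list.
#' @export
coexpression_params <- function(soft_power = 16L,
                                min_module_size = 50L,
                                deep_split = 2L,
                                edge_weight_threshold = 0.01,
                                tf_edge_threshold = 0.02,
                                deep_split_quantiles = c(0.95, 0.92, 0.90, 0.88),
                                merge_cor_min = 0.3,
                                merge_alpha = 0.01) {
  if (soft_power < 1) abort("soft_power must be >= 1")
  if (!deep_split %in% 0:3) abort("deep_split must be in 0..3")
  assert_scalar_num(edge_weight_threshold, "edge_weight_threshold", 0, 1)
  assert_scalar_num(tf_edge_threshold, "tf_edge_threshold", 0, 1)
  structure(list(soft_power = as.integer(soft_power),
                 network_type = "signed",
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 edge_weight_threshold = edge_weight_threshold,
                 tf_edge_threshold = tf_edge_threshold,
                 deep_split_quantiles = deep_split_quantiles,
                 merge_cor_min = merge_cor_min,
                 merge_alpha = merge_alpha),
            class = "coexpression_params")
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with Pearson correlation; the diagonal
#' is 1. Anticorrelated genes get near-zero adjacency (signed network).
#'
#' @param expr genes x samples expression matrix with no constant rows.
#' @param beta soft power.
#' @return symmetric adjacency matrix in [0, 1].
#' @export
signed_adjacency <- function(expr, beta) {
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    abort("constant gene(s) in expression matrix: %s",
          paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power the signed adjacency is built, connectivity
#' `k_i = sum_j a_ij (j != i)` computed, log10(k) binned, and
#' log10 frequency regressed on log10 mean connectivity per bin.
#' `r_squared` is the plain fit R^2 (in [0, 1]); `signed_r_squared`
#' negates it when the slope is positive, so only decreasing degree
#' distributions can be recommended. The recommended power is the smallest
#' with signed R^2 >= `target_r2`; if none reaches it, the power with the
#' highest signed R^2.
#'
#' @param expr genes x samples matrix (>= 20 genes); constant genes are
#'   dropped with a warning.
#' @param candidate_powers integer vector of powers to scan.
#' @param n_bins connectivity histogram bins (default 10).
#' @param target_r2 fit threshold for the recommendation (default 0.85).
#' @return tibble(power, r_squared, signed_r_squared, slope,
#'   mean_connectivity) with attribute `recommended_power`.
#' @export
scale_free_fit <- function(expr, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                           n_bins = 10L, target_r2 = 0.85) {
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 20) abort("scale-free fit needs >= 20 non-constant genes")
  s <- (1 + stats::cor(t(expr))) / 2
  diag(s) <- 0
  fit_one <- function(beta) {
    k <- rowSums(s^beta)
    k <- k[k > 0]
    br <- seq(min(log10(k)), max(log10(k)), length.out = n_bins + 1L)
    bin <- cut(log10(k), breaks = br, include.lowest = TRUE)
    kmean <- tapply(k, bin, mean)
    freq <- tapply(k, bin, length) / length(k)
    ok <- !is.na(kmean) & freq > 0
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    r2 <- summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2])
    c(r2 = r2, signed = -sign(slope) * r2, slope = slope, meank = mean(k))
  }
  res <- t(vapply(candidate_powers, fit_one, numeric(4)))
  out <- tibble::tibble(
    power = candidate_powers,
    r_squared = res[, "r2"],
    signed_r_squared = res[, "signed"],
    slope = res[, "slope"],
    mean_connectivity = res[, "meank"]
  )
  hit <- which(out$signed_r_squared >= target_r2)
  attr(out, "recommended_power") <-
    if (length(hit)) out$power[hit[1]] else out$power[which.max(out$signed_r_squared)]
  out
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with connectivity `k_i = sum_u a_iu` over u != i and the sum
#' over shared neighbours u excluding i and j; `TOM_ii = 1`.
#'
#' @param adjacency symmetric adjacency matrix in [0, 1], unit diagonal.
#' @return symmetric TOM matrix in [0, 1], unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a  # l_ij = sum_{u != i,j} a_iu a_uj (diag of a is 0)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' cut at the midpoint of the largest gap in the sorted merge heights,
#' searched only among heights at or below the quantile indexed by
#' `deep_split` (the `deep_split_quantiles` map). Tight co-expression
#' modules finish merging well below the heights at which unclustered
#' genes aggregate, so the dominant height gap separates the two regimes;
#' capping the search lower (larger deep_split) can only move the cut
#' down, hence yields at least as many raw clusters. Clusters smaller than
#' `min_module_size` are absorbed into the retained module whose eigengene
#' they correlate with best, provided that correlation reaches
#' `merge_cor_min` and is significant at `merge_alpha`; otherwise their
#' genes are left unassigned (module 0). Module ids are assigned by
#' decreasing size.
#'
#' @param tom TOM matrix.
#' @param params a [coexpression_params()].
#' @param expr genes x samples expression matrix (needed for the
#'   eigengene-based merge of small clusters).
#' @return named integer vector: gene -> module id (0 = unassigned), with
#'   attribute `n_raw_clusters`.
#' @export
detect_modules <- function(tom, params, expr) {
  genes <- rownames(tom)
  if (nrow(tom) < 2) abort("need at least 2 genes")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  q <- params$deep_split_quantiles[params$deep_split + 1L]
  hh <- sort(h$height)
  cap <- stats::quantile(hh, q, names = FALSE)
  cand <- which(hh <= cap)
  cand <- cand[cand < length(hh)]  # need a gap above each candidate
  if (!length(cand)) cand <- 1L
  gaps <- hh[cand + 1L] - hh[cand]
  i <- cand[which.max(gaps)]
  cut_h <- (hh[i] + hh[i + 1L]) / 2
  raw <- stats::cutree(h, h = cut_h)
  sizes <- table(raw)
  big <- as.integer(names(sizes)[sizes >= params$min_module_size])
  labels <- stats::setNames(rep(0L, length(genes)), genes)
  if (length(big) == 0) {
    message("no cluster reaches min_module_size; all genes unassigned")
    attr(labels, "n_raw_clusters") <- length(sizes)
    return(labels)
  }
  for (i in seq_along(big)) labels[raw == big[i]] <- i
  # absorb small clusters by eigengene correlation, single pass; the
  # correlation must clear both the flat floor and significance at
  # merge_alpha for the available sample size
  me_big <- module_eigengene(expr, labels)
  df <- ncol(expr) - 2L
  tcrit <- stats::qt(1 - params$merge_alpha / 2, df)
  r_floor <- max(params$merge_cor_min, sqrt(tcrit^2 / (tcrit^2 + df)))
  small <- setdiff(as.integer(names(sizes)), big)
  for (cl in small) {
    members <- genes[raw == cl]
    me_small <- module_eigengene(
      expr, stats::setNames(rep(1L, length(members)), members))
    cors <- as.vector(stats::cor(me_small[, 1], me_big))
    cors[is.na(cors)] <- -1
    if (max(cors) >= r_floor)
      labels[members] <- as.integer(sub("^ME", "", colnames(me_big)[which.max(cors)]))
  }
  # relabel by decreasing size (0 stays 0)
  tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  mode(labels) <- "integer"
  attr(labels, "n_raw_clusters") <- length(sizes)
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression (unit-norm over samples), sign-oriented
#' so that its correlation with the module's average expression profile is
#' positive. A single-gene module's eigengene is that gene's standardized
#' profile (normalized to unit norm).
#'
#' @param expr genes x samples matrix.
#' @param assignment named integer vector gene -> module (0 ignored).
#' @return samples x modules matrix, columns named `ME<id>`, unit norm.
#' @export
module_eigengene <- function(expr, assignment) {
  mods <- sort(unique(assignment[assignment > 0]))
  if (!length(mods)) abort("assignment contains no modules")
  me <- vapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    x <- expr[members, , drop = FALSE]
    xs <- t(scale(t(x)))  # standardize each gene over samples
    xs[is.na(xs)] <- 0    # constant member contributes nothing
    v <- svd(xs, nu = 0, nv = 1)$v[, 1]
    if (stats::sd(colMeans(x)) > 0 && stats::cor(v, colMeans(x)) < 0) v <- -v
    v / sqrt(sum(v^2))
  }, numeric(ncol(expr)))
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  me
}

#' Module-trait correlation
#'
#' Each group becomes a one-hot sample indicator; the matrix of Pearson
#' correlations between eigengenes and indicators is returned with
#' two-sided Student p-values.
#'
#' @param eigengenes samples x modules matrix from [module_eigengene()].
#' @param samples sample sheet tibble (rows matching the eigengene rows).
#' @return list(cor, p): modules x groups matrices.
#' @export
module_trait_correlation <- function(eigengenes, samples) {
  stopifnot(nrow(eigengenes) == nrow(samples))
  groups <- sort(unique(samples$group))
  ind <- vapply(groups, function(g) as.numeric(samples$group == g),
                numeric(nrow(samples)))
  r <- stats::cor(eigengenes, ind)
  n <- nrow(eigengenes)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  dimnames(r) <- dimnames(p) <- list(colnames(eigengenes), groups)
  list(cor = r, p = p)
}

#' Module membership and gene significance
#'
#' MM(gene) is the Pearson correlation of the gene's profile with its own
#' module's eigengene (NA for unassigned genes); GS(gene, group) is the
#' correlation with the group's one-hot indicator.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes samples x modules matrix.
#' @param assignment gene -> module vector.
#' @param samples sample sheet tibble.
#' @return tibble(gene, module, mm, gs_<group>...).
#' @export
module_membership <- function(expr, eigengenes, assignment, samples) {
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  eigengenes <- eigengenes[match(colnames(expr), rownames(eigengenes)), ,
                           drop = FALSE]
  genes <- rownames(expr)
  mm <- rep(NA_real_, length(genes))
  for (m in sort(unique(assignment[assignment > 0]))) {
    members <- names(assignment)[assignment == m]
    me <- eigengenes[, paste0("ME", m)]
    mm[match(members, genes)] <-
      as.vector(stats::cor(t(expr[members, , drop = FALSE]), me))
  }
  groups <- sort(unique(samples$group))
  gs <- vapply(groups, function(g) {
    as.vector(stats::cor(t(expr), as.numeric(samples$group == g)))
  }, numeric(length(genes)))
  out <- tibble::tibble(
    gene = genes,
    module = unname(assignment[genes]),
    mm = mm
  )
  colnames(gs) <- paste0("gs_", groups)
  tibble::as_tibble(cbind(out, gs))
}

#' Extract weighted edges from the TOM
#'
#' The general network keeps every gene pair with TOM strictly above
#' `edge_weight_threshold`; the TF-centric network keeps pairs involving
#' at least one TF with TOM at or above `tf_edge_threshold`. Edge weight
#' is the TOM value; endpoints carry their module labels. TF degree is the
#' number of incident edges in the TF-centric network.
#'
#' @param tom TOM matrix.
#' @param assignment gene -> module vector.
#' @param params a [coexpression_params()].
#' @param tf_list TF symbols.
#' @return list(general, tf, tf_degree): two edge tibbles
#'   (gene_a, gene_b, weight, module_a, module_b) and a named degree
#'   vector over TFs.
#' @export
extract_module_edges <- function(tom, assignment, params, tf_list) {
  genes <- rownames(tom)
  ut <- upper.tri(tom)
  idx <- which(ut & tom > params$edge_weight_threshold, arr.ind = TRUE)
  make_edges <- function(idx) {
    tibble::tibble(
      gene_a = genes[idx[, 1]],
      gene_b = genes[idx[, 2]],
      weight = tom[idx],
      module_a = unname(assignment[genes[idx[, 1]]]),
      module_b = unname(assignment[genes[idx[, 2]]])
    )
  }
  general <- make_edges(idx)
  is_tf <- genes %in% tf_list
  tf_pair <- outer(is_tf, is_tf, `|`)
  idx_tf <- which(ut & tf_pair & tom >= params$tf_edge_threshold,
                  arr.ind = TRUE)
  tf_edges <- make_edges(idx_tf)
  deg <- stats::setNames(integer(sum(is_tf)), genes[is_tf])
  inc <- table(c(tf_edges$gene_a, tf_edges$gene_b))
  common <- intersect(names(deg), names(inc))
  deg[common] <- as.integer(inc[common])
  list(general = general, tf = tf_edges, tf_degree = deg)
}
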