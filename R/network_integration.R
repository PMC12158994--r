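# Three-source regulatory-network integration: local TF-target enrichment
# against a ChIP-derived gene-set library, curated-repository lookup,
# merging with co-expression edges, TF-only projection with centrality,
# expression-breadth classes and promoter-accessibility annotation.

#' TF-target enrichment of a DEG list against a gene-set library
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per TF on the
#' 2x2 table (DEG & targets, DEG \\ targets, targets \\ DEG, rest) over the
#' analysis universe. A TF is kept when its raw p-value is at most
#' `p_cutoff` and the TF itself is expressed in the group of interest
#' (mean log2 CPM >= `expression_floor`). Kept TFs contribute directed
#' edges to each overlapping DEG.
#'
#' @param deg_list character vector of differentially expressed genes
#'   (intersected with the universe).
#' @param chea_sets interaction table (regulator, target, ...) or a named
#'   list TF -> targets.
#' @param universe background gene set (typically the filtered genes).
#' @param expr log2 CPM matrix (for the expression filter).
#' @param samples sample sheet tibble.
#' @param group the lineage group whose DEGs are tested.
#' @param p_cutoff raw p-value cutoff (default 0.05). BH FDR is reported
#'   alongside but not used for the keep flag.
#' @param expression_floor minimum mean log2 CPM of the TF in the group.
#' @return list(result, edges): the enrichment table
#'   (tf, overlap, set_size, deg_count, universe, p_value, fdr, kept) and
#'   the directed edge tibble (regulator, target, source = "chea").
#' @export
enrich_tf_targets <- function(deg_list, chea_sets, universe, expr, samples,
                              group, p_cutoff = 0.05, expression_floor = 1) {
  sets <- if (is.data.frame(chea_sets)) {
    split(chea_sets$target, chea_sets$regulator)
  } else chea_sets
  deg <- intersect(deg_list, universe)
  if (!length(deg)) {
    return(list(result = tibble::tibble(
      tf = character(), overlap = integer(), set_size = integer(),
      deg_count = integer(), universe = integer(), p_value = numeric(),
      fdr = numeric(), kept = logical()),
      edges = tibble::tibble(regulator = character(), target = character(),
                             source = character())))
  }
  in_grp <- samples$sample_id[samples$group == group]
  n_u <- length(universe)
  rows <- lapply(names(sets), function(tf) {
    targets <- intersect(unique(sets[[tf]]), universe)
    ov <- length(intersect(deg, targets))
    p <- stats::phyper(ov - 1, length(targets), n_u - length(targets),
                       length(deg), lower.tail = FALSE)
    list(tf = tf, overlap = ov, set_size = length(targets),
         deg_count = length(deg), p = p,
         hits = intersect(deg, targets))
  })
  tf_expr <- vapply(names(sets), function(tf) {
    if (tf %in% rownames(expr)) mean(expr[tf, in_grp]) else NA_real_
  }, 0)
  p <- vapply(rows, `[[`, 0, "p")
  result <- tibble::tibble(
    tf = vapply(rows, `[[`, "", "tf"),
    overlap = vapply(rows, `[[`, 0L, "overlap"),
    set_size = vapply(rows, `[[`, 0L, "set_size"),
    deg_count = vapply(rows, `[[`, 0L, "deg_count"),
    universe = n_u,
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    kept = p <= p_cutoff & !is.na(tf_expr) & tf_expr >= expression_floor
  )
  kept_rows <- rows[result$kept]
  edges <- tibble::tibble(
    regulator = rep(vapply(kept_rows, `[[`, "", "tf"),
                    vapply(kept_rows, function(r) length(r$hits), 0L)),
    target = unlist(lapply(kept_rows, `[[`, "hits")) %||% character(0),
    source = "chea"
  )
  list(result = result, edges = unique(edges))
}

#' Look up curated regulator/target interactions for expressed TFs
#'
#' @param expressed_tfs TFs considered expressed in the analysis.
#' @param regnet_table interaction tibble (regulator, target, ...).
#' @param universe analysis gene universe targets must belong to.
#' @return tibble(regulator, target, source = "regnet"), deduplicated.
#' @export
regnet_lookup <- function(expressed_tfs, regnet_table, universe) {
  keep <- regnet_table$regulator %in% expressed_tfs &
    regnet_table$target %in% universe
  unique(tibble::tibble(
    regulator = regnet_table$regulator[keep],
    target = regnet_table$target[keep],
    source = "regnet"
  ))
}

#' Merge co-expression, ChIP-derived and curated edges into one network
#'
#' Co-expression edges are undirected and stored with lexicographically
#' ordered endpoints; database edges are directed. Edges with the same
#' (from, to) key collapse to a single edge carrying the union of source
#' tags (sorted, "+"-joined) and the maximum weight. A directed pair whose
#' unordered endpoints match an existing undirected co-expression edge is
#' folded into that edge (the source tag is added, undirected storage
#' preserved). The merge is invariant to input row order.
#'
#' @param wgcna_edges tibble(gene_a, gene_b, weight) or NULL.
#' @param chea_edges tibble(regulator, target, source) or NULL.
#' @param regnet_edges tibble(regulator, target, source) or NULL.
#' @param tf_list TF symbols for the node table.
#' @return a `regulatory_network`: list(nodes, edges) where edges has
#'   columns from, to, directed, sources, weight.
#' @export
merge_networks <- function(wgcna_edges = NULL, chea_edges = NULL,
                           regnet_edges = NULL, tf_list = character(0)) {
  und <- NULL
  if (!is.null(wgcna_edges) && nrow(wgcna_edges)) {
    a <- pmin(wgcna_edges$gene_a, wgcna_edges$gene_b)
    b <- pmax(wgcna_edges$gene_a, wgcna_edges$gene_b)
    und <- tibble::tibble(from = a, to = b, weight = wgcna_edges$weight)
    und <- und[order(und$from, und$to, -und$weight), ]
    und <- und[!duplicated(paste(und$from, und$to)), ]
    und$sources <- "wgcna"
  }
  dir_in <- rbind(
    if (!is.null(chea_edges) && nrow(chea_edges))
      chea_edges[, c("regulator", "target", "source")],
    if (!is.null(regnet_edges) && nrow(regnet_edges))
      regnet_edges[, c("regulator", "target", "source")]
  )
  dir <- NULL
  if (!is.null(dir_in) && nrow(dir_in)) {
    dir_in <- unique(dir_in)
    key <- paste(dir_in$regulator, dir_in$target)
    src <- vapply(split(dir_in$source, key),
                  function(s) paste(sort(unique(s)), collapse = "+"), "")
    uk <- unique(key)
    first <- match(uk, key)
    dir <- tibble::tibble(
      from = dir_in$regulator[first],
      to = dir_in$target[first],
      weight = NA_real_,
      sources = unname(src[uk])
    )
  }
  if (!is.null(und) && !is.null(dir) && nrow(dir)) {
    ukey <- paste(und$from, und$to)
    dkey <- paste(pmin(dir$from, dir$to), pmax(dir$from, dir$to))
    hit <- match(dkey, ukey)
    fold <- !is.na(hit)
    for (i in which(fold)) {
      j <- hit[i]
      und$sources[j] <- paste(sort(unique(c(
        strsplit(und$sources[j], "+", fixed = TRUE)[[1]],
        strsplit(dir$sources[i], "+", fixed = TRUE)[[1]]))), collapse = "+")
    }
    dir <- dir[!fold, , drop = FALSE]
  }
  edges <- rbind(
    if (!is.null(und))
      tibble::tibble(from = und$from, to = und$to, directed = FALSE,
                     sources = und$sources, weight = und$weight),
    if (!is.null(dir) && nrow(dir))
      tibble::tibble(from = dir$from, to = dir$to, directed = TRUE,
                     sources = dir$sources, weight = dir$weight)
  )
  if (is.null(edges) || !nrow(edges)) abort("no edges to merge")
  edges <- edges[order(edges$from, edges$to, edges$directed), ]
  nodes_sym <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(node = nodes_sym, is_tf = nodes_sym %in% tf_list)
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory network: %d nodes (%d TFs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges)))
  src <- table(unlist(strsplit(x$edges$sources, "+", fixed = TRUE)))
  cat("  source tags:",
      paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
  invisible(x)
}

# incident-edge counts for every node of a network (directed and
# undirected edges each count once per incident endpoint)
network_degree <- function(network) {
  nodes <- network$nodes$node
  deg <- stats::setNames(integer(length(nodes)), nodes)
  inc <- table(c(network$edges$from, network$edges$to))
  deg[names(inc)] <- as.integer(inc)
  deg
}

#' Project a regulatory network onto its TFs
#'
#' Keeps only TF-TF edges. Every TF node is retained (even if isolated in
#' the projection) and annotated with `full_degree`, its incident-edge
#' count in the full merged network (TF-gene plus TF-TF), which is the
#' node-size scale of the TF-only view. Projection is idempotent.
#'
#' @param network a `regulatory_network`.
#' @param tf_list TF symbols.
#' @return a `regulatory_network` over TFs with node column `full_degree`.
#' @export
tf_projection <- function(network, tf_list) {
  deg <- network_degree(network)
  is_tf <- network$nodes$node %in% tf_list | network$nodes$is_tf
  tf_nodes <- network$nodes$node[is_tf]
  keep <- network$edges$from %in% tf_nodes & network$edges$to %in% tf_nodes
  nodes <- tibble::tibble(
    node = tf_nodes, is_tf = TRUE,
    full_degree = unname(deg[tf_nodes])
  )
  structure(list(nodes = nodes,
                 edges = network$edges[keep, , drop = FALSE]),
            class = "regulatory_network")
}

#' Classify a TF's expression breadth across lineage groups
#'
#' "specific": significantly differentially expressed (workflow
#' thresholds) in exactly one group; "general": in every group;
#' "multi-group": otherwise; "none": never significant (excluded from
#' breadth-based coloring).
#'
#' @param de_tables named list of DE tibbles, one per non-stem group.
#' @param gene gene/TF symbol.
#' @return one of "specific", "multi-group", "general", "none".
#' @export
classify_expression_breadth <- function(de_tables, gene) {
  sig <- vapply(de_tables, function(de) {
    i <- match(gene, de$gene)
    !is.na(i) && isTRUE(de$significant[i])
  }, TRUE)
  n <- sum(sig)
  if (n == 0) "none"
  else if (n == 1) "specific"
  else if (n == length(de_tables)) "general"
  else "multi-group"
}

#' Mean promoter accessibility of each TF's interactors
#'
#' For every TF node and every group, the mean OCR activity over the TF's
#' network interactors (neighbours regardless of direction). Interactors
#' absent from the accessibility table contribute 0 to the mean (the
#' denominator is the full interactor count). The cross-group mean of
#' these values is the "OCR activity of interactors" summary column.
#'
#' @param network a `regulatory_network`.
#' @param accessibility tibble(gene, group, ocr_activity).
#' @param tfs TFs to annotate (default: TF nodes of the network).
#' @return tibble(tf, group, mean_interactor_ocr).
#' @export
annotate_ocr <- function(network, accessibility,
                         tfs = network$nodes$node[network$nodes$is_tf]) {
  groups <- sort(unique(accessibility$group))
  ockey <- paste(accessibility$gene, accessibility$group)
  rows <- lapply(tfs, function(tf) {
    nb <- unique(c(network$edges$to[network$edges$from == tf],
                   network$edges$from[network$edges$to == tf]))
    nb <- setdiff(nb, tf)
    if (!length(nb)) {
      message(sprintf("TF %s has no interactors; OCR annotation is 0", tf))
      return(tibble::tibble(tf = tf, group = groups, mean_interactor_ocr = 0))
    }
    vals <- vapply(groups, function(g) {
      oc <- accessibility$ocr_activity[match(paste(nb, g), ockey)]
      oc[is.na(oc)] <- 0
      mean(oc)
    }, 0)
    tibble::tibble(tf = tf, group = groups, mean_interactor_ocr = unname(vals))
  })
  do.call(rbind, rows)
}
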