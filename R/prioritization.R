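# Candidate-TF table assembly and ranking: one row per (group, TF) with
# expression, fold change, specificity, centrality, source set and
# interactor accessibility, plus a known/unknown flag and a rank-sum
# ordering of the unknown candidates.

#' Select candidate TFs per group from module membership
#'
#' For each group, take the module(s) with the highest module-trait
#' correlation (ties keep all tied modules), then every TF in those
#' modules with MM >= `threshold`. Groups whose best correlation is not
#' positive yield an empty set with a warning.
#'
#' @param mm_gs tibble from [module_membership()].
#' @param module_trait_cor list(cor, p) from [module_trait_correlation()].
#' @param tf_list TF symbols.
#' @param threshold MM cutoff (default 0.5; the boundary is inclusive).
#' @param tol tie tolerance on the trait correlation (default 1e-12).
#' @return named list: group -> character vector of TFs.
#' @export
select_candidates <- function(mm_gs, module_trait_cor, tf_list,
                              threshold = 0.5, tol = 1e-12) {
  cors <- module_trait_cor$cor
  groups <- colnames(cors)
  out <- lapply(stats::setNames(groups, groups), function(g) {
    col <- cors[, g]
    best <- max(col)
    if (best <= 0) {
      warning(sprintf("group %s has no positively correlated module", g))
      return(character(0))
    }
    mods <- as.integer(sub("^ME", "", rownames(cors)[col >= best - tol]))
    sel <- mm_gs$gene %in% tf_list & mm_gs$module %in% mods &
      !is.na(mm_gs$mm) & mm_gs$mm >= threshold
    sort(mm_gs$gene[sel])
  })
  out
}

render_sources <- function(sources) {
  if (is.na(sources) || !nzchar(sources)) return(NA_character_)
  disp <- c(chea = "chea", regnet = "RegNet", wgcna = "WGCNA")
  tags <- unique(unlist(strsplit(sources, "+", fixed = TRUE)))
  shown <- unname(disp[tags])
  paste(shown[order(tolower(shown))], collapse = "_")
}

#' Assemble the candidate-TF table
#'
#' A pure join of the upstream results: per (group, TF) row with mean
#' expression in the group (log2 CPM), log2 fold change vs. the stem
#' group, lineage specificity, merged-network degree (plus the TF-centric
#' co-expression degree), the "_"-joined source-type label of the TF's
#' edges (e.g. "RegNet_WGCNA"), the cross-group mean interactor OCR
#' activity, the TF's module membership, and the known/unknown flag from a
#' curated list. TFs missing from an upstream table get NA with a warning.
#'
#' @param selected named list group -> TFs from [select_candidates()].
#' @param expr log2 CPM matrix.
#' @param samples sample sheet tibble.
#' @param de_tables named list of DE tibbles per group.
#' @param specificity_table tibble from [specificity_score()].
#' @param network merged `regulatory_network`.
#' @param ocr_annotation tibble from [annotate_ocr()].
#' @param known_list NULL or tibble(tf, group, ...) of TFs with reported
#'   function (curated input, not computed).
#' @param mm_gs optional tibble from [module_membership()] for the MM column.
#' @param tf_degree optional named vector of TF-centric co-expression
#'   degrees from [extract_module_edges()].
#' @return tibble, one row per (group, tf), unranked.
#' @export
build_candidate_table <- function(selected, expr, samples, de_tables,
                                  specificity_table, network,
                                  ocr_annotation, known_list = NULL,
                                  mm_gs = NULL, tf_degree = NULL) {
  deg_full <- network_degree(network)
  ekey_from <- network$edges$from
  ekey_to <- network$edges$to
  spkey <- paste(specificity_table$gene, specificity_table$group)
  rows <- list()
  for (g in names(selected)) {
    for (tf in selected[[g]]) {
      in_grp <- samples$sample_id[samples$group == g]
      expr_val <- if (tf %in% rownames(expr)) mean(expr[tf, in_grp]) else NA_real_
      de <- de_tables[[g]]
      lfc <- if (!is.null(de)) de$log2fc[match(tf, de$gene)] else NA_real_
      spec <- specificity_table$specificity[match(paste(tf, g), spkey)]
      dg <- if (tf %in% names(deg_full)) unname(deg_full[tf]) else NA_integer_
      src <- network$edges$sources[ekey_from == tf | ekey_to == tf]
      net_types <- if (length(src))
        render_sources(paste(unique(unlist(strsplit(src, "+", fixed = TRUE))),
                             collapse = "+")) else NA_character_
      ocr_tf <- ocr_annotation$mean_interactor_ocr[ocr_annotation$tf == tf]
      ocr <- if (length(ocr_tf)) mean(ocr_tf) else NA_real_
      mm <- if (!is.null(mm_gs)) mm_gs$mm[match(tf, mm_gs$gene)] else NA_real_
      known <- !is.null(known_list) &&
        any(known_list$tf == tf & known_list$group == g)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, tf = tf,
        expression_log2cpm_in_group = expr_val,
        log2fc_vs_stem = lfc,
        specificity = spec,
        degree = dg,
        degree_wgcna = if (!is.null(tf_degree) && tf %in% names(tf_degree))
          unname(tf_degree[tf]) else NA_integer_,
        network_types = net_types,
        ocr_activity_of_interactors = ocr,
        mm = mm,
        known = known
      )
    }
  }
  if (!length(rows)) abort("no candidates selected for any group")
  out <- do.call(rbind, rows)
  n_na <- sum(is.na(out$log2fc_vs_stem)) + sum(is.na(out$specificity)) +
    sum(is.na(out$degree)) + sum(is.na(out$ocr_activity_of_interactors))
  if (n_na > 0)
    warning(sprintf("%d missing upstream value(s) in the candidate table", n_na))
  out
}

#' Rank unknown candidate TFs within each group
#'
#' Rank-sum aggregation: within each group, every unknown TF gets the sum
#' of its within-group descending ranks over six criteria (expression,
#' log2FC, specificity, degree, number of evidence sources, interactor OCR
#' activity), optionally weighted; a lower rank-sum is better. Final ties
#' are broken lexicographically by TF symbol. Known TFs keep their rows
#' but receive no rank. Rank aggregation makes the ordering invariant to
#' monotone transformations of any single criterion.
#'
#' @param table tibble from [build_candidate_table()].
#' @param weights named numeric vector over the six criteria (default all
#'   1); names: expression, log2fc, specificity, degree, n_sources, ocr.
#' @return the table with columns n_sources, rank_sum and rank, ordered by
#'   group then rank.
#' @export
rank_candidates <- function(table, weights = NULL) {
  if (!nrow(table)) abort("candidate table is empty")
  w <- c(expression = 1, log2fc = 1, specificity = 1, degree = 1,
         n_sources = 1, ocr = 1)
  if (!is.null(weights)) w[names(weights)] <- weights
  table$n_sources <- ifelse(
    is.na(table$network_types), 0L,
    lengths(strsplit(table$network_types, "_", fixed = TRUE)))
  crit <- list(
    expression = table$expression_log2cpm_in_group,
    log2fc = table$log2fc_vs_stem,
    specificity = table$specificity,
    degree = as.numeric(table$degree),
    n_sources = as.numeric(table$n_sources),
    ocr = table$ocr_activity_of_interactors
  )
  table$rank_sum <- NA_real_
  table$rank <- NA_integer_
  for (g in unique(table$group)) {
    idx <- which(table$group == g & !table$known)
    if (!length(idx)) next
    rs <- numeric(length(idx))
    for (nm in names(crit)) {
      x <- crit[[nm]][idx]
      x[is.na(x)] <- -Inf  # missing evidence ranks worst
      rs <- rs + w[[nm]] * rank(-x, ties.method = "average")
    }
    table$rank_sum[idx] <- rs
    ord <- order(rs, table$tf[idx])
    table$rank[idx[ord]] <- seq_along(idx)
  }
  table[order(table$group, is.na(table$rank), table$rank, table$tf), ]
}
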