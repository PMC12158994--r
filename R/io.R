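# Readers reject malformed input rather than silently coercing it; every
# symbol column passes through normalize_symbols() exactly once at load.

#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene symbols, remaining columns one sample each.
#' Duplicate gene ids, negative or non-integer values are errors.
#'
#' @param path TSV file.
#' @return integer matrix, genes in rows (rownames), samples in columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("count file needs a gene column plus >= 1 sample")
  genes <- normalize_symbols(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    abort("duplicate gene id(s) in %s: %s", path, paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric count value in %s", path)
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    abort("counts in %s must be nonnegative integers", path)
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s))
    abort("duplicate sample id(s) in %s: %s", path, paste(dup_s, collapse = ", "))
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with gene rownames.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, group, subgroup)
#'
#' @param path TSV with header; `subgroup` defaults to `group` if absent.
#' @param counts optional count matrix; when given, every count column must
#'   appear in the sheet (unknown samples are reported by name).
#' @return tibble with columns sample_id, group, subgroup.
#' @export
read_samples <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("sample sheet %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  if (is.null(df$subgroup)) df$subgroup <- df$group
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    abort("duplicate sample_id(s): %s", paste(dup, collapse = ", "))
  samples <- tibble::as_tibble(df[, c("sample_id", "group", "subgroup")])
  if (!is.null(counts)) {
    unknown <- setdiff(colnames(counts), samples$sample_id)
    if (length(unknown))
      abort("samples present in counts but absent from annotation: %s",
            paste(unknown, collapse = ", "))
  }
  samples
}

#' Read a TF symbol list (one symbol per line)
#' @param path text file.
#' @return character vector of unique, normalized TF symbols.
#' @export
read_tf_list <- function(path) {
  x <- normalize_symbols(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read a TSS table (gene, chrom, pos, strand); positions are 1-based
#' @param path TSV with header.
#' @return tibble(gene, chrom, pos, strand).
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("TSS table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  df$gene <- normalize_symbols(df$gene)
  if (any(df$pos < 1)) abort("TSS positions are 1-based and must be >= 1")
  tibble::as_tibble(df[, need])
}

#' Read peak intervals from a 5-column BED file
#'
#' Columns: chrom, start, end, name, score. Coordinates are 0-based
#' half-open. The name column carries the cell-group label of the peak
#' (per-group scores in one file). Malformed lines are reported with their
#' line number.
#'
#' @param path BED file.
#' @return tibble(chrom, start, end, group, score).
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(i) {
    f <- fields[[i]]
    if (length(f) < 5)
      abort("malformed BED line %d: expected 5 tab-separated fields, got %d",
            i, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start)
      abort("malformed BED line %d: invalid interval [%s, %s)", i, f[2], f[3])
    if (is.na(score)) abort("malformed BED line %d: non-numeric score", i)
    list(chrom = f[1], start = start, end = end, group = f[4], score = score)
  }
  rows <- lapply(seq_along(fields), parse_one)
  tibble::tibble(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    group = vapply(rows, `[[`, "", "group"),
    score = vapply(rows, `[[`, 0, "score")
  )
}

#' Write peaks as 5-column BED (chrom, start, end, name = group, score)
#' @param peaks tibble as from [read_peaks_bed()].
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start,
                     peaks$end, peaks$group,
                     vapply(peaks$score, format, "", digits = 15,
                            trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Aggregate peak scores around TSSs into per-gene, per-group accessibility
#'
#' For every gene and every group present in the peak table, the open
#' chromatin (OCR) activity is the mean score of that group's peaks
#' overlapping the symmetric window `[tss - window_bp, tss + window_bp)`
#' (0-based half-open; strand is ignored). Genes with no overlapping peak
#' get 0. The result is invariant to peak row order.
#'
#' @param peaks tibble(chrom, start, end, group, score), 0-based half-open.
#' @param tss tibble(gene, chrom, pos, strand), 1-based positions.
#' @param window_bp half-width of the promoter window in bp (default 1000).
#' @return tibble(gene, group, ocr_activity) with one row per pair.
#' @export
aggregate_ocr_at_tss <- function(peaks, tss, window_bp = 1000L) {
  assert_scalar_num(window_bp, "window_bp", lower = 0)
  groups <- sort(unique(peaks$group))
  if (window_bp == 0) {  # empty half-open window overlaps nothing
    return(tibble::tibble(
      gene = rep(tss$gene, times = length(groups)),
      group = rep(groups, each = nrow(tss)),
      ocr_activity = 0
    ))
  }
  acc <- matrix(0, nrow = nrow(tss), ncol = length(groups),
                dimnames = list(tss$gene, groups))
  n <- matrix(0L, nrow = nrow(tss), ncol = length(groups),
              dimnames = list(tss$gene, groups))
  for (chr in unique(tss$chrom)) {
    ti <- which(tss$chrom == chr)
    pi <- which(peaks$chrom == chr)
    if (!length(pi)) next
    # 0-based half-open -> 1-based closed for IRanges
    t0 <- tss$pos[ti] - 1L
    win <- IRanges::IRanges(start = t0 - window_bp + 1L, end = t0 + window_bp)
    pk <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    hits <- IRanges::findOverlaps(win, pk)
    if (!length(hits)) next
    qi <- ti[S4Vectors::queryHits(hits)]
    si <- pi[S4Vectors::subjectHits(hits)]
    gcol <- match(peaks$group[si], groups)
    for (k in seq_along(qi)) {
      acc[qi[k], gcol[k]] <- acc[qi[k], gcol[k]] + peaks$score[si[k]]
      n[qi[k], gcol[k]] <- n[qi[k], gcol[k]] + 1L
    }
  }
  mean_score <- ifelse(n > 0, acc / pmax(n, 1L), 0)
  tibble::tibble(
    gene = rep(tss$gene, times = length(groups)),
    group = rep(groups, each = nrow(tss)),
    ocr_activity = as.vector(mean_score)
  )
}

#' Read a gene-set library in GMT format into an interaction table
#'
#' Each GMT row is one TF followed by a description field and its target
#' genes (ChIP-enrichment library convention).
#'
#' @param path GMT file.
#' @return tibble(regulator, target, source = "chea"), deduplicated.
#' @export
read_gmt_interactions <- function(path) {
  sets <- fgsea::gmtPathways(path)
  tab <- tibble::tibble(
    regulator = normalize_symbols(rep(names(sets), lengths(sets))),
    target = normalize_symbols(unlist(sets, use.names = FALSE)),
    source = "chea"
  )
  unique(tab)
}

#' Write a named list of target sets as GMT
#' @param sets named list, TF -> character vector of targets.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(tf) {
    paste(c(tf, "synthetic", sets[[tf]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a curated regulator/target edge table
#' @param path TSV with columns regulator, target.
#' @return tibble(regulator, target, source = "regnet"), deduplicated.
#' @export
read_regnet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("regulator", "target"), names(df))
  if (length(miss))
    abort("edge table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab <- tibble::tibble(
    regulator = normalize_symbols(df$regulator),
    target = normalize_symbols(df$target),
    source = "regnet"
  )
  unique(tab)
}

#' Export a regulatory network in SIF format
#'
#' One line per edge: `regulator <tag> target`, where the tag is the
#' "+"-joined sorted source set (e.g. `chea+regnet`).
#'
#' @param network a `regulatory_network` (see [merge_networks()]).
#' @param path output file.
#' @export
write_network_sif <- function(network, path) {
  e <- network$edges
  if (!nrow(e)) abort("cannot export an empty network")
  writeLines(sprintf("%s\t%s\t%s", e$from, e$sources, e$to), path)
  invisible(path)
}

#' Export a regulatory network as GraphML (Cytoscape-readable)
#'
#' Node attributes: is_tf plus any extra node-table columns (full_degree,
#' expression_class, ...). Edge attributes: sources, weight, directed.
#' [read_network_graphml()] reproduces the node and edge sets.
#'
#' @param network a `regulatory_network`.
#' @param path output file.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    d = network$edges, directed = TRUE,
    vertices = as.data.frame(network$nodes)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import a GraphML regulatory network written by this package
#' @param path GraphML file.
#' @return a `regulatory_network` list (nodes, edges).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
  names(nodes)[names(nodes) == "name"] <- "node"
  edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  if (!is.null(edges$directed)) edges$directed <- as.logical(edges$directed)
  if (!is.null(nodes$is_tf)) nodes$is_tf <- as.logical(nodes$is_tf)
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}
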