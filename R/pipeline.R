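# Stage orchestration: simulate -> preprocess -> specificity -> wgcna ->
# integrate -> prioritize, each re-runnable in isolation from on-disk
# artifacts, with a JSON manifest (parameter snapshot + input/output file
# hashes) per stage. All randomness flows from the single config seed.

PIPELINE_STAGES <- c("simulate", "preprocess", "specificity", "wgcna",
                     "integrate", "prioritize")

#' Pipeline configuration
#'
#' Collects every tunable parameter of the workflow plus input paths. When
#' `sim` is a [sim_config()], the simulate stage generates the inputs;
#' otherwise the paths in `inputs` are used (counts, samples, tf_list,
#' peaks, tss, chea, regnet, optionally known_tfs).
#'
#' @param sim a [sim_config()] or NULL for real inputs.
#' @param inputs named list of input file paths (used when `sim` is NULL,
#'   or to override individual simulated files).
#' @param stem_group reference group for differential expression.
#' @param min_count,sample_fraction,min_total gene filter parameters.
#' @param prior_count log2 CPM prior.
#' @param fdr,lfc_tf,lfc_other DE significance thresholds.
#' @param power soft power for the all-lineage co-expression run.
#' @param dc_power soft power for the DC-subset re-run (default 12).
#' @param min_module_size,deep_split,edge_threshold,tf_edge_threshold
#'   module detection and edge extraction parameters.
#' @param mm_threshold module-membership cutoff for candidate selection.
#' @param p_cutoff,expression_floor enrichment filter parameters.
#' @param ocr_window promoter half-window in bp for OCR aggregation.
#' @param specificity_scale "log2cpm" (default) or "cpm".
#' @param ranking_weights optional named weight vector for
#'   [rank_candidates()].
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            inputs = list(),
                            stem_group = "Stem",
                            min_count = 10, sample_fraction = 0.70,
                            min_total = 100, prior_count = 2,
                            fdr = 0.05, lfc_tf = 0.585, lfc_other = 1,
                            power = 16L, dc_power = 12L,
                            min_module_size = 50L, deep_split = 2L,
                            edge_threshold = 0.01, tf_edge_threshold = 0.02,
                            mm_threshold = 0.5,
                            p_cutoff = 0.05, expression_floor = 1,
                            ocr_window = 1000L,
                            specificity_scale = "log2cpm",
                            ranking_weights = NULL,
                            seed = 1L) {
  if (!is.null(sim)) {
    sim$seed <- as.integer(seed)
    validate_sim_config(sim)
  }
  specificity_scale <- match.arg(specificity_scale, c("log2cpm", "cpm"))
  structure(list(
    sim = sim, inputs = inputs, stem_group = stem_group,
    min_count = min_count, sample_fraction = sample_fraction,
    min_total = min_total, prior_count = prior_count,
    fdr = fdr, lfc_tf = lfc_tf, lfc_other = lfc_other,
    power = as.integer(power), dc_power = as.integer(dc_power),
    min_module_size = as.integer(min_module_size),
    deep_split = as.integer(deep_split),
    edge_threshold = edge_threshold,
    tf_edge_threshold = tf_edge_threshold,
    mm_threshold = mm_threshold, p_cutoff = p_cutoff,
    expression_floor = expression_floor,
    ocr_window = as.integer(ocr_window),
    specificity_scale = specificity_scale,
    ranking_weights = ranking_weights,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a `sim:` block (keys
#' mirroring [sim_config()]) switches the simulate stage on, `sim: ~`
#' (null) switches it off in favour of the `inputs:` paths.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$module_specs))
      y$sim$module_specs <- do.call(rbind.data.frame, y$sim$module_specs)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

input_path <- function(config, outdir, name, default) {
  config$inputs[[name]] %||% file.path(outdir, default)
}

require_artifact <- function(path, stage_hint) {
  if (!file.exists(path))
    abort("missing artifact %s; run the '%s' stage first", path, stage_hint)
  path
}

write_manifest <- function(outdir, stage, config, inputs, outputs) {
  cfg <- config
  cfg$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("hemaTFnet")),
    parameters = unclass(cfg),
    input_md5 = as.list(stats::setNames(
      tools::md5sum(inputs[file.exists(inputs)]),
      basename(inputs[file.exists(inputs)]))),
    output_md5 = as.list(stats::setNames(
      tools::md5sum(outputs[file.exists(outputs)]),
      basename(outputs[file.exists(outputs)])))
  )
  jsonlite::write_json(manifest,
                       file.path(outdir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

#' Run one pipeline stage against on-disk artifacts
#'
#' Stages: simulate, preprocess, specificity, wgcna, integrate,
#' prioritize. Each stage reads the upstream artifacts it needs from
#' `outdir` (or the configured input paths), writes its outputs and a
#' `manifest_<stage>.json` recording parameters and file hashes. A missing
#' upstream artifact raises an error naming the stage to run.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param outdir working/output directory.
#' @return invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage, config, outdir) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  switch(stage,
    simulate = {
      if (is.null(config$sim))
        abort("config has no simulation block; supply input paths instead")
      write_simulation(config$sim, outdir)
      outs <- fp(c("counts.tsv", "samples.tsv", "tf_list.txt", "peaks.bed",
                   "tss.tsv", "chea_like.gmt", "regnet_like.tsv", "truth.json"))
      write_manifest(outdir, stage, config, character(0), outs)
      invisible(outs)
    },
    preprocess = {
      counts <- read_counts(require_artifact(
        input_path(config, outdir, "counts", "counts.tsv"), "simulate"))
      samples <- read_samples(require_artifact(
        input_path(config, outdir, "samples", "samples.tsv"), "simulate"),
        counts = counts)
      tf_list <- read_tf_list(require_artifact(
        input_path(config, outdir, "tf_list", "tf_list.txt"), "simulate"))
      filtered <- filter_genes(counts, config$min_count,
                               config$sample_fraction, config$min_total)
      expr <- normalize_log2cpm(filtered, config$prior_count)
      write_counts(filtered, fp("filtered_counts.tsv"))
      write_tsv_plain(data.frame(gene = rownames(expr), expr,
                                 check.names = FALSE), fp("log2cpm.tsv"))
      groups <- setdiff(sort(unique(samples$group)), config$stem_group)
      de_all <- do.call(rbind, lapply(groups, function(g)
        differential_expression(filtered, samples, g, config$stem_group,
                                tf_list, config$fdr, config$lfc_tf,
                                config$lfc_other, expr = expr)))
      write_tsv_plain(de_all, fp("de_all.tsv"))
      outs <- fp(c("filtered_counts.tsv", "log2cpm.tsv", "de_all.tsv"))
      write_manifest(outdir, stage, config,
                     c(input_path(config, outdir, "counts", "counts.tsv"),
                       input_path(config, outdir, "samples", "samples.tsv")),
                     outs)
      invisible(outs)
    },
    specificity = {
      expr <- read_matrix_tsv(require_artifact(fp("log2cpm.tsv"), "preprocess"))
      if (config$specificity_scale == "cpm") expr <- 2^expr
      samples <- read_samples(
        input_path(config, outdir, "samples", "samples.tsv"))
      spec <- specificity_score(expr, samples)
      write_tsv_plain(spec, fp("specificity.tsv"))
      write_manifest(outdir, stage, config, fp("log2cpm.tsv"),
                     fp("specificity.tsv"))
      invisible(fp("specificity.tsv"))
    },
    wgcna = {
      expr <- read_matrix_tsv(require_artifact(fp("log2cpm.tsv"), "preprocess"))
      samples <- read_samples(
        input_path(config, outdir, "samples", "samples.tsv"))
      tf_list <- read_tf_list(
        input_path(config, outdir, "tf_list", "tf_list.txt"))
      run_wgcna_stage(expr, samples, tf_list, config, outdir, prefix = "")
    },
    integrate = {
      expr <- read_matrix_tsv(require_artifact(fp("log2cpm.tsv"), "preprocess"))
      samples <- read_samples(
        input_path(config, outdir, "samples", "samples.tsv"))
      tf_list <- read_tf_list(
        input_path(config, outdir, "tf_list", "tf_list.txt"))
      universe <- rownames(expr)
      de_all <- utils::read.delim(require_artifact(fp("de_all.tsv"),
                                                   "preprocess"))
      de_tables <- split(tibble::as_tibble(de_all), de_all$group)
      chea <- read_gmt_interactions(require_artifact(
        input_path(config, outdir, "chea", "chea_like.gmt"), "simulate"))
      regnet <- read_regnet(require_artifact(
        input_path(config, outdir, "regnet", "regnet_like.tsv"), "simulate"))
      tf_edges <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("tf_edges.tsv"), "wgcna")))

      enr_all <- list(); chea_edges <- list()
      for (g in names(de_tables)) {
        deg <- de_tables[[g]]$gene[de_tables[[g]]$significant]
        enr <- enrich_tf_targets(deg, chea, universe, expr, samples, g,
                                 config$p_cutoff, config$expression_floor)
        enr$result$group <- g
        enr_all[[g]] <- enr$result
        chea_edges[[g]] <- enr$edges
      }
      enr_tab <- do.call(rbind, enr_all)
      chea_edges <- unique(do.call(rbind, chea_edges))
      grp_means <- vapply(sort(unique(samples$group)), function(g) {
        rowMeans(expr[, samples$sample_id[samples$group == g], drop = FALSE])
      }, numeric(nrow(expr)))
      expressed_tfs <- intersect(
        tf_list, universe[apply(grp_means, 1, max) >= config$expression_floor])
      regnet_edges <- regnet_lookup(expressed_tfs, regnet, universe)
      wgcna_edges <- tf_edges[, c("gene_a", "gene_b", "weight")]
      network <- merge_networks(wgcna_edges, chea_edges, regnet_edges, tf_list)
      network$nodes$expression_class <- vapply(network$nodes$node, function(n)
        if (n %in% tf_list) classify_expression_breadth(de_tables, n)
        else NA_character_, "")
      peaks <- read_peaks_bed(require_artifact(
        input_path(config, outdir, "peaks", "peaks.bed"), "simulate"))
      tss <- read_tss(require_artifact(
        input_path(config, outdir, "tss", "tss.tsv"), "simulate"))
      accessibility <- aggregate_ocr_at_tss(peaks, tss, config$ocr_window)
      ocr_ann <- suppressMessages(annotate_ocr(network, accessibility))
      tf_net <- tf_projection(network, tf_list)

      write_tsv_plain(enr_tab, fp("enrichment.tsv"))
      write_tsv_plain(network$edges, fp("network_edges.tsv"))
      write_tsv_plain(network$nodes, fp("network_nodes.tsv"))
      write_network_sif(network, fp("network.sif"))
      write_network_graphml(network, fp("network.graphml"))
      write_tsv_plain(tf_net$nodes, fp("tf_network_nodes.tsv"))
      write_tsv_plain(tf_net$edges, fp("tf_network_edges.tsv"))
      write_tsv_plain(accessibility, fp("accessibility.tsv"))
      write_tsv_plain(ocr_ann, fp("ocr_annotation.tsv"))
      outs <- fp(c("enrichment.tsv", "network_edges.tsv", "network_nodes.tsv",
                   "network.sif", "network.graphml", "tf_network_nodes.tsv",
                   "tf_network_edges.tsv", "accessibility.tsv",
                   "ocr_annotation.tsv"))
      write_manifest(outdir, stage, config,
                     fp(c("log2cpm.tsv", "de_all.tsv", "tf_edges.tsv")), outs)
      invisible(outs)
    },
    prioritize = {
      expr <- read_matrix_tsv(require_artifact(fp("log2cpm.tsv"), "preprocess"))
      samples <- read_samples(
        input_path(config, outdir, "samples", "samples.tsv"))
      tf_list <- read_tf_list(
        input_path(config, outdir, "tf_list", "tf_list.txt"))
      mm_gs <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("mm_gs.tsv"), "wgcna")))
      mtc_cor <- read_matrix_tsv(require_artifact(fp("module_trait_cor.tsv"),
                                                  "wgcna"))
      de_all <- utils::read.delim(require_artifact(fp("de_all.tsv"),
                                                   "preprocess"))
      de_tables <- split(tibble::as_tibble(de_all), de_all$group)
      spec <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("specificity.tsv"), "specificity")))
      edges <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("network_edges.tsv"), "integrate")))
      nodes <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("network_nodes.tsv"), "integrate")))
      network <- structure(list(nodes = nodes, edges = edges),
                           class = "regulatory_network")
      ocr_ann <- tibble::as_tibble(utils::read.delim(
        require_artifact(fp("ocr_annotation.tsv"), "integrate")))
      tf_deg <- utils::read.delim(require_artifact(fp("tf_degree.tsv"),
                                                   "wgcna"))
      tf_degree <- stats::setNames(tf_deg$degree, tf_deg$tf)
      known <- NULL
      kp <- config$inputs$known_tfs
      if (!is.null(kp)) {
        known <- utils::read.delim(kp, stringsAsFactors = FALSE)
        known$tf <- normalize_symbols(known$tf)
      }
      # candidates are nominated for differentiated lineages only; the
      # stem group is the DE reference and has no fold change of its own
      mtc_cor <- mtc_cor[, setdiff(colnames(mtc_cor), config$stem_group),
                         drop = FALSE]
      selected <- select_candidates(mm_gs, list(cor = mtc_cor), tf_list,
                                    config$mm_threshold)
      tab <- build_candidate_table(selected, expr, samples, de_tables, spec,
                                   network, ocr_ann, known_list = known,
                                   mm_gs = mm_gs, tf_degree = tf_degree)
      ranked <- rank_candidates(tab, config$ranking_weights)
      write_tsv_plain(ranked, fp("candidates.tsv"))
      write_manifest(outdir, stage, config,
                     fp(c("mm_gs.tsv", "module_trait_cor.tsv",
                          "network_edges.tsv", "ocr_annotation.tsv")),
                     fp("candidates.tsv"))
      invisible(fp("candidates.tsv"))
    }
  )
}

# shared by the all-lineage wgcna stage and the DC re-run
run_wgcna_stage <- function(expr, samples, tf_list, config, outdir,
                            prefix = "", power = config$power,
                            group_col = "group") {
  fp <- function(f) file.path(outdir, paste0(prefix, f))
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s) before network build",
                    sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  params <- coexpression_params(
    soft_power = power,
    min_module_size = config$min_module_size,
    deep_split = config$deep_split,
    edge_weight_threshold = config$edge_threshold,
    tf_edge_threshold = config$tf_edge_threshold
  )
  adj <- signed_adjacency(expr, params$soft_power)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, params, expr)
  strat <- samples
  strat$group <- strat[[group_col]]
  if (!any(assignment > 0)) {
    write_tsv_plain(data.frame(gene = names(assignment),
                               module = unname(assignment)),
                    fp("modules.tsv"))
    abort("no modules detected; nothing to analyze downstream")
  }
  me <- module_eigengene(expr, assignment)
  me <- me[match(colnames(expr), rownames(me)), , drop = FALSE]
  mtc <- module_trait_correlation(
    me[match(strat$sample_id, rownames(me)), , drop = FALSE], strat)
  mm_gs <- module_membership(expr, me, assignment, strat)
  edges <- extract_module_edges(tom, assignment, params, tf_list)
  write_tsv_plain(data.frame(gene = names(assignment),
                             module = unname(assignment)), fp("modules.tsv"))
  write_tsv_plain(data.frame(module = rownames(mtc$cor), mtc$cor,
                             check.names = FALSE), fp("module_trait_cor.tsv"))
  write_tsv_plain(data.frame(module = rownames(t(me)), t(me),
                             check.names = FALSE), fp("eigengenes.tsv"))
  write_tsv_plain(mm_gs, fp("mm_gs.tsv"))
  write_tsv_plain(edges$general, fp("wgcna_edges.tsv"))
  write_tsv_plain(edges$tf, fp("tf_edges.tsv"))
  write_tsv_plain(data.frame(tf = names(edges$tf_degree),
                             degree = unname(edges$tf_degree)),
                  fp("tf_degree.tsv"))
  outs <- fp(c("modules.tsv", "module_trait_cor.tsv", "eigengenes.tsv",
               "mm_gs.tsv", "wgcna_edges.tsv", "tf_edges.tsv",
               "tf_degree.tsv"))
  write_manifest(outdir, paste0(prefix, "wgcna"), config,
                 file.path(outdir, "log2cpm.tsv"), outs)
  invisible(outs)
}

#' Run the full pipeline
#'
#' Executes simulate (when configured), preprocess, specificity, wgcna,
#' integrate and prioritize in order. Re-running with an unchanged config
#' reproduces every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, the path of candidates.tsv.
#' @export
run_pipeline <- function(config, outdir) {
  stages <- PIPELINE_STAGES
  if (is.null(config$sim)) stages <- setdiff(stages, "simulate")
  for (s in stages) run_stage(s, config, outdir)
  invisible(file.path(outdir, "candidates.tsv"))
}

#' Re-run the co-expression network on the DC compartment
#'
#' Restricts the sample sheet to the stem group plus all samples whose
#' group or subgroup label contains "DC", rebuilds the signed network with
#' the smaller-cohort soft power (`dc_power`, default 12), and writes the
#' same wgcna-stage artifacts under a `dc_` prefix. Module-trait
#' correlations use the subgroup labels so DC subsets can be told apart.
#'
#' @param config a [pipeline_config()].
#' @param outdir directory holding the preprocess artifacts.
#' @return invisibly, the paths written.
#' @export
run_dc_mode <- function(config, outdir) {
  fp <- function(f) file.path(outdir, f)
  expr <- read_matrix_tsv(require_artifact(fp("log2cpm.tsv"), "preprocess"))
  samples <- read_samples(input_path(config, outdir, "samples", "samples.tsv"))
  tf_list <- read_tf_list(input_path(config, outdir, "tf_list", "tf_list.txt"))
  is_dc <- grepl("DC", samples$group, ignore.case = TRUE) |
    grepl("DC", samples$subgroup, ignore.case = TRUE)
  if (!any(is_dc))
    abort("sample sheet contains no DC groups; dc-mode needs at least one")
  keep <- samples[is_dc | samples$group == config$stem_group, ]
  run_wgcna_stage(expr[, keep$sample_id, drop = FALSE], keep, tf_list,
                  config, outdir, prefix = "dc_", power = config$dc_power,
                  group_col = "subgroup")
}
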