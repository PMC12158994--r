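#' Simulation configuration for synthetic hematopoietic datasets
#'
#' Describes a seeded synthetic study with the statistical structure the
#' downstream analysis assumes: lineage groups with replicates, planted
#' co-expression modules tied to driver groups, group-restricted TFs with
#' known target sets, negative-binomial counts, and TSS-proximal chromatin
#' accessibility coupled to group-restricted expression.
#'
#' The defaults emulate a desk-scaled version of a sorted-population bulk
#' RNA-seq compendium: six lineage groups (stem cells plus five
#' differentiated lineages), eight replicates per group, 600 genes of which
#' 60 are transcription factors, and three planted modules of 60 genes
#' driven by the B, T and NK groups. Counts follow a gamma-Poisson
#' (negative binomial) model with dispersion 0.04 (biological CV 0.2,
#' typical of inbred-mouse sorted populations); module co-expression is
#' induced by one shared latent factor per module on the log scale.
#'
#' @param n_groups number of lineage groups (first label is the stem group).
#' @param group_labels labels for the groups; length `n_groups`.
#' @param replicates_per_group samples per group.
#' @param n_genes total genes (TFs included).
#' @param n_tfs number of TF symbols among the genes.
#' @param module_specs data.frame with columns `size`, `driver_group`,
#'   `latent_strength` (one row per planted module).
#' @param tfs_per_module how many of each module's genes are TFs; these are
#'   the planted group-specific TFs.
#' @param group_effect_log2 mean log2 shift of group-restricted genes in
#'   their driver group.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param mean_library_size expected per-sample library size.
#' @param tf_target_out_degree targets per TF in the planted truth.
#' @param db_false_positive_rate,db_false_negative_rate noise rates applied
#'   when emitting the synthetic TF-target databases.
#' @param accessibility_dropout probability that a group-restricted gene
#'   lacks an elevated TSS peak in its group (default 0.2, mirroring the
#'   observation that some lineage-specific TFs have closed promoters).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_groups = 6L,
                       group_labels = c("Stem", "B", "T", "NK", "ILC", "DC")[seq_len(n_groups)],
                       replicates_per_group = 8L,
                       n_genes = 600L,
                       n_tfs = 60L,
                       module_specs = data.frame(
                         size = c(60L, 60L, 60L),
                         driver_group = c("B", "T", "NK"),
                         latent_strength = c(0.8, 0.8, 0.8)
                       ),
                       tfs_per_module = 8L,
                       group_effect_log2 = 3,
                       nb_dispersion = 0.04,
                       mean_library_size = 5e5,
                       tf_target_out_degree = 30L,
                       db_false_positive_rate = 0.1,
                       db_false_negative_rate = 0.1,
                       accessibility_dropout = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    group_labels = as.character(group_labels),
    replicates_per_group = as.integer(replicates_per_group),
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    module_specs = module_specs,
    tfs_per_module = as.integer(tfs_per_module),
    group_effect_log2 = group_effect_log2,
    nb_dispersion = nb_dispersion,
    mean_library_size = mean_library_size,
    tf_target_out_degree = as.integer(tf_target_out_degree),
    db_false_positive_rate = db_false_positive_rate,
    db_false_negative_rate = db_false_negative_rate,
    accessibility_dropout = accessibility_dropout,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$group_labels) != cfg$n_groups)
    abort("group_labels must have length n_groups (%d)", cfg$n_groups)
  ms <- cfg$module_specs
  if (!is.null(ms) && nrow(ms) > 0) {
    if (!all(c("size", "driver_group", "latent_strength") %in% names(ms)))
      abort("module_specs needs columns size, driver_group, latent_strength")
    if (sum(ms$size) > cfg$n_genes)
      abort("sum of module sizes (%d) exceeds n_genes (%d)",
            sum(ms$size), cfg$n_genes)
    bad <- setdiff(ms$driver_group, cfg$group_labels)
    if (length(bad))
      abort("driver_group(s) not among group labels: %s",
            paste(bad, collapse = ", "))
    if (any(ms$latent_strength < 0 | ms$latent_strength > 1))
      abort("latent_strength must lie in [0, 1]")
    if (any(ms$size < cfg$tfs_per_module))
      abort("each module must be at least tfs_per_module genes")
  }
  if (cfg$n_tfs > cfg$n_genes) abort("n_tfs must not exceed n_genes")
  assert_scalar_num(cfg$group_effect_log2, "group_effect_log2", lower = 0)
  assert_scalar_num(cfg$nb_dispersion, "nb_dispersion", lower = 1e-12)
  assert_scalar_num(cfg$db_false_positive_rate, "db_false_positive_rate", 0, 1)
  assert_scalar_num(cfg$db_false_negative_rate, "db_false_negative_rate", 0, 1)
  assert_scalar_num(cfg$accessibility_dropout, "accessibility_dropout", 0, 1)
  invisible(cfg)
}

sim_gene_ids <- function(cfg) {
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  others <- sprintf("G%04d", seq_len(cfg$n_genes - cfg$n_tfs))
  c(tfs, others)
}

#' Generate a synthetic count matrix with planted structure
#'
#' Counts are negative-binomially distributed around
#' `exp(baseline + latent_strength * Z_module + group_effect_log2 * ln2 *
#' restricted)`, where `Z_module` is a standard-normal latent factor shared
#' by all genes of a module (one draw per sample) and `restricted`
#' indicates that the gene belongs to a module whose driver group matches
#' the sample's group. Expected per-sample totals equal
#' `mean_library_size`.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (gene x sample integer matrix),
#'   `samples` (tibble: sample_id, group, subgroup) and `truth` (planted
#'   structure: module of each gene, restricted group of each gene,
#'   group-specific TFs, TF target sets, gene/TF universes).
#' @export
generate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_gene_ids(config)
  tfs <- genes[seq_len(config$n_tfs)]
  groups <- config$group_labels
  samples <- tibble::tibble(
    sample_id = paste0(rep(groups, each = config$replicates_per_group), "_",
                       rep(seq_len(config$replicates_per_group), config$n_groups)),
    group = rep(groups, each = config$replicates_per_group),
    subgroup = rep(groups, each = config$replicates_per_group)
  )
  n_s <- nrow(samples)

  ms <- config$module_specs
  n_mod <- if (is.null(ms)) 0L else nrow(ms)
  module_of <- stats::setNames(rep(0L, config$n_genes), genes)
  restricted <- stats::setNames(rep(NA_character_, config$n_genes), genes)
  # module m takes tfs_per_module TFs and (size - tfs_per_module) other genes
  next_tf <- 1L
  next_gene <- config$n_tfs + 1L
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      mem_tf <- genes[next_tf:(next_tf + config$tfs_per_module - 1L)]
      n_other <- ms$size[m] - config$tfs_per_module
      mem_other <- genes[next_gene:(next_gene + n_other - 1L)]
      next_tf <- next_tf + config$tfs_per_module
      next_gene <- next_gene + n_other
      members <- c(mem_tf, mem_other)
      module_of[members] <- m
      restricted[members] <- ms$driver_group[m]
    }
  }

  baseline_log2 <- stats::runif(config$n_genes, 4, 10)
  ln2 <- log(2)
  log_mu <- matrix(baseline_log2 * ln2, nrow = config$n_genes, ncol = n_s)
  dimnames(log_mu) <- list(genes, samples$sample_id)
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      z <- stats::rnorm(n_s)
      idx <- which(module_of == m)
      log_mu[idx, ] <- log_mu[idx, ] +
        matrix(ms$latent_strength[m] * z, nrow = length(idx), ncol = n_s,
               byrow = TRUE)
    }
    for (m in seq_len(n_mod)) {
      idx <- which(module_of == m)
      in_grp <- samples$group == ms$driver_group[m]
      log_mu[idx, in_grp] <- log_mu[idx, in_grp] + config$group_effect_log2 * ln2
    }
  }
  mu <- exp(log_mu)
  mu <- sweep(mu, 2, colSums(mu), "/") * config$mean_library_size
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = config$n_genes, dimnames = dimnames(mu)
  )
  storage.mode(counts) <- "integer"

  group_specific_tfs <- lapply(stats::setNames(groups, groups), function(g) {
    if (n_mod == 0) return(character(0))
    mods <- which(ms$driver_group == g)
    intersect(names(module_of)[module_of %in% mods], tfs)
  })
  planted_tfs <- unlist(group_specific_tfs, use.names = FALSE)
  tf_targets <- lapply(stats::setNames(tfs, tfs), function(tf) {
    m <- module_of[[tf]]
    pool <- if (m > 0) setdiff(names(module_of)[module_of == m], tf)
            else setdiff(genes, tf)
    sort(sample(pool, min(config$tf_target_out_degree, length(pool))))
  })

  truth <- list(
    genes = genes,
    tfs = tfs,
    true_module_of_gene = module_of,
    restricted_group_of_gene = restricted,
    group_specific_tfs = group_specific_tfs,
    decoy_tfs = setdiff(tfs, planted_tfs),
    tf_targets = tf_targets,
    accessible_gene_groups = NULL
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Generate synthetic TSS-proximal accessibility
#'
#' Every gene receives one TSS on a single synthetic chromosome and one
#' peak per lineage group centred on the TSS. Genes restricted to a group
#' carry an elevated peak score in that group with probability
#' `1 - accessibility_dropout`; all other (gene, group) pairs get a
#' background-level score.
#'
#' @param truth the `truth` element returned by [generate_counts()].
#' @param config the same [sim_config()].
#' @return list with `peaks` (tibble: chrom, start, end, group, score;
#'   0-based half-open), `tss` (tibble: gene, chrom, pos, strand; 1-based),
#'   `accessibility` (tibble: gene, group, ocr_activity) and the `truth`
#'   updated with realized `accessible_gene_groups`.
#' @export
generate_accessibility <- function(truth, config) {
  set.seed(config$seed + 1L)
  genes <- truth$genes
  groups <- config$group_labels
  n_g <- length(genes)
  tss <- tibble::tibble(
    gene = genes,
    chrom = "chrSYN",
    pos = 10000L * seq_len(n_g),
    strand = rep(c("+", "-"), length.out = n_g)
  )
  grid <- expand.grid(gene = genes, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  score <- stats::runif(nrow(grid), 0.5, 2)
  is_restricted <- !is.na(truth$restricted_group_of_gene[grid$gene]) &
    truth$restricted_group_of_gene[grid$gene] == grid$group
  kept <- stats::runif(nrow(grid)) >= config$accessibility_dropout
  elev <- is_restricted & kept
  score[elev] <- stats::runif(sum(elev), 6, 10)
  pos0 <- tss$pos[match(grid$gene, tss$gene)] - 1L
  peaks <- tibble::tibble(
    chrom = "chrSYN",
    start = pos0 - 200L,
    end = pos0 + 200L,
    group = grid$group,
    score = score
  )
  accessibility <- tibble::tibble(
    gene = grid$gene, group = grid$group, ocr_activity = score
  )
  truth$accessible_gene_groups <- accessibility
  list(peaks = peaks, tss = tss, accessibility = accessibility, truth = truth)
}

#' Emit noisy synthetic TF-target databases
#'
#' Produces a ChIP-enrichment-style gene-set library (one target set per
#' TF) and a curated-repository-style regulator/target edge table, both
#' derived from the planted truth with configurable false-positive and
#' false-negative rates. Each true target is dropped with probability
#' `db_false_negative_rate`; false positives are added as a binomial draw
#' (size = number of true targets, prob = `db_false_positive_rate`) of
#' random non-target genes. Both outputs are internally deduplicated.
#'
#' @param truth truth from [generate_counts()].
#' @param config the same [sim_config()].
#' @return list with `chea` (named list TF -> character vector of targets)
#'   and `regnet` (tibble: regulator, target).
#' @export
generate_tf_target_db <- function(truth, config) {
  set.seed(config$seed + 2L)
  fp <- config$db_false_positive_rate
  fn <- config$db_false_negative_rate
  noisy_set <- function(tf) {
    true <- truth$tf_targets[[tf]]
    keep <- true[stats::runif(length(true)) >= fn]
    n_fp <- stats::rbinom(1L, length(true), fp)
    pool <- setdiff(truth$genes, c(true, tf))
    fps <- if (n_fp > 0) sample(pool, min(n_fp, length(pool))) else character(0)
    sort(unique(c(keep, fps)))
  }
  chea <- lapply(stats::setNames(truth$tfs, truth$tfs), noisy_set)
  regnet_sets <- lapply(stats::setNames(truth$tfs, truth$tfs), noisy_set)
  regnet <- tibble::tibble(
    regulator = rep(names(regnet_sets), lengths(regnet_sets)),
    target = unlist(regnet_sets, use.names = FALSE)
  )
  regnet <- unique(regnet)
  list(chea = chea, regnet = regnet)
}

#' Write a full synthetic study to disk
#'
#' Writes counts.tsv, samples.tsv, tf_list.txt, peaks.bed, tss.tsv,
#' chea_like.gmt, regnet_like.tsv and truth.json under `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_counts(config)
  acc <- generate_accessibility(sim$truth, config)
  db <- generate_tf_target_db(acc$truth, config)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(acc$truth$tfs, file.path(dir, "tf_list.txt"))
  write_peaks_bed(acc$peaks, file.path(dir, "peaks.bed"))
  utils::write.table(acc$tss, file.path(dir, "tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(db$chea, file.path(dir, "chea_like.gmt"))
  utils::write.table(db$regnet, file.path(dir, "regnet_like.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- acc$truth
  truth$true_module_of_gene <- as.list(truth$true_module_of_gene)
  truth$restricted_group_of_gene <- as.list(truth$restricted_group_of_gene)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(list(counts = sim$counts, samples = sim$samples,
                 truth = acc$truth, peaks = acc$peaks, tss = acc$tss,
                 accessibility = acc$accessibility, chea = db$chea,
                 regnet = db$regnet))
}
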