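test_that("generators are seeded and deterministic", {
  cfg <- small_sim_config(seed = 1L)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$tf_targets, b$truth$tf_targets)
  acc1 <- generate_accessibility(a$truth, cfg)
  acc2 <- generate_accessibility(b$truth, cfg)
  expect_identical(acc1$peaks, acc2$peaks)
  db1 <- generate_tf_target_db(a$truth, cfg)
  db2 <- generate_tf_target_db(a$truth, cfg)
  expect_identical(db1$chea, db2$chea)
  expect_identical(db1$regnet, db2$regnet)
})

test_that("counts are nonnegative integers with library sizes near target", {
  cfg <- small_sim_config(seed = 2L)
  sim <- generate_counts(cfg)
  expect_true(is.integer(sim$counts))
  expect_true(all(sim$counts >= 0))
  expect_equal(dim(sim$counts), c(300L, 30L))
  expect_equal(nrow(sim$samples), 30L)
  lib <- colSums(sim$counts)
  # NB column sums concentrate tightly around the configured library size
  expect_true(all(abs(lib - cfg$mean_library_size) <
                    0.1 * cfg$mean_library_size))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100L, module_specs = data.frame(
    size = 120L, driver_group = "B", latent_strength = 0.5)),
    "module sizes")
  expect_error(sim_config(module_specs = data.frame(
    size = 60L, driver_group = "Myeloid", latent_strength = 0.5)),
    "driver_group")
  expect_error(sim_config(n_tfs = 700L), "n_tfs")
  expect_error(sim_config(db_false_positive_rate = 1.5),
               "db_false_positive_rate")
})

test_that("null configuration yields uncorrelated modules (Monte Carlo)", {
  # no latent factor, no group effect: within-module correlation vanishes
  rbar <- vapply(1:20, function(rep) {
    cfg <- sim_config(
      n_genes = 500L, n_tfs = 0L, replicates_per_group = 10L,
      module_specs = data.frame(size = 50L, driver_group = "B",
                                latent_strength = 0),
      tfs_per_module = 0L, group_effect_log2 = 0, seed = 100L + rep
    )
    sim <- generate_counts(cfg)
    members <- names(which(sim$truth$true_module_of_gene == 1L))
    cc <- stats::cor(t(log1p(sim$counts[members, ])))
    mean(cc[upper.tri(cc)])
  }, 0)
  expect_lt(abs(mean(rbar)), 0.05)
})

test_that("a strong latent factor separates module correlation from background", {
  cfg <- sim_config(
    n_genes = 400L, n_tfs = 0L, tfs_per_module = 0L,
    replicates_per_group = 10L, group_effect_log2 = 0,
    module_specs = data.frame(size = 50L, driver_group = "B",
                              latent_strength = 0.9),
    seed = 21L
  )
  sim <- generate_counts(cfg)
  lg <- log1p(sim$counts)
  members <- names(which(sim$truth$true_module_of_gene == 1L))
  backgrounds <- sample(names(which(sim$truth$true_module_of_gene == 0L)), 100)
  cm <- stats::cor(t(lg[members, ]))
  cb <- stats::cor(t(lg[backgrounds, ]))
  expect_gt(mean(cm[upper.tri(cm)]),
            stats::quantile(cb[upper.tri(cb)], 0.95))
})

test_that("planted log2FC grows with the configured group effect", {
  med_fc <- vapply(c(1, 2, 3), function(eff) {
    cfg <- sim_config(group_effect_log2 = eff, seed = 31L,
                      replicates_per_group = 5L)
    sim <- generate_counts(cfg)
    expr <- normalize_log2cpm(sim$counts)
    restr <- sim$truth$restricted_group_of_gene
    restr <- restr[!is.na(restr)]
    fc <- vapply(seq_along(restr), function(i) {
      g <- names(restr)[i]
      in_g <- sim$samples$sample_id[sim$samples$group == restr[i]]
      ref <- sim$samples$sample_id[sim$samples$group == "Stem"]
      mean(expr[g, in_g]) - mean(expr[g, ref])
    }, 0)
    stats::median(fc)
  }, 0)
  expect_true(all(diff(med_fc) > 0))
})

test_that("accessibility elevates restricted genes and honours dropout limits", {
  cfg0 <- small_sim_config(seed = 4L)
  cfg0$accessibility_dropout <- 0
  sim <- generate_counts(cfg0)
  acc <- generate_accessibility(sim$truth, cfg0)
  restr <- sim$truth$restricted_group_of_gene
  restr <- restr[!is.na(restr)]
  key <- paste(acc$accessibility$gene, acc$accessibility$group)
  for (g in names(restr)[1:25]) {
    own <- acc$accessibility$ocr_activity[key == paste(g, restr[g])]
    others <- acc$accessibility$ocr_activity[
      acc$accessibility$gene == g & acc$accessibility$group != restr[g]]
    expect_true(all(own > others))
  }
  # full dropout: restricted genes stay at background level everywhere
  cfg1 <- cfg0
  cfg1$accessibility_dropout <- 1
  acc1 <- generate_accessibility(sim$truth, cfg1)
  expect_true(all(acc1$accessibility$ocr_activity < 2 + 1e-9))
})

test_that("written accessibility round-trips through BED/TSS aggregation", {
  cfg <- small_sim_config(seed = 5L)
  sim <- generate_counts(cfg)
  acc <- generate_accessibility(sim$truth, cfg)
  dir <- withr::local_tempdir()
  write_peaks_bed(acc$peaks, file.path(dir, "p.bed"))
  utils::write.table(acc$tss, file.path(dir, "t.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  peaks <- read_peaks_bed(file.path(dir, "p.bed"))
  tss <- read_tss(file.path(dir, "t.tsv"))
  agg <- aggregate_ocr_at_tss(peaks, tss, window_bp = 1000L)
  key <- paste(agg$gene, agg$group)
  ref <- acc$accessibility
  expect_equal(agg$ocr_activity[match(paste(ref$gene, ref$group), key)],
               ref$ocr_activity, tolerance = 1e-9)
})

test_that("database noise rates behave at their limits and are reproducible", {
  cfg <- small_sim_config(seed = 6L)
  sim <- generate_counts(cfg)
  cfg0 <- cfg
  cfg0$db_false_positive_rate <- 0
  cfg0$db_false_negative_rate <- 0
  db0 <- generate_tf_target_db(sim$truth, cfg0)
  expect_identical(db0$chea, sim$truth$tf_targets)
  cfg1 <- cfg
  cfg1$db_false_negative_rate <- 1
  db1 <- generate_tf_target_db(sim$truth, cfg1)
  for (tf in names(db1$chea)) {
    expect_length(intersect(db1$chea[[tf]], sim$truth$tf_targets[[tf]]), 0)
  }
  # noisy sets: per-TF Jaccard against truth reproducible across calls
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  dba <- generate_tf_target_db(sim$truth, cfg)
  dbb <- generate_tf_target_db(sim$truth, cfg)
  ja <- vapply(names(dba$chea),
               function(tf) jaccard(dba$chea[[tf]], sim$truth$tf_targets[[tf]]), 0)
  jb <- vapply(names(dbb$chea),
               function(tf) jaccard(dbb$chea[[tf]], sim$truth$tf_targets[[tf]]), 0)
  expect_identical(ja, jb)
  expect_true(all(ja > 0.5) && all(ja < 1))
})
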