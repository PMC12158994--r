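fisher_fixture <- function() {
  set.seed(17)
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = rep(c("B", "Stem"), each = 2), subgroup = group
  )
  universe <- sprintf("G%03d", 1:100)
  expr <- matrix(5, length(universe) + 1, 4,
                 dimnames = list(c(universe, "TF1"), samples$sample_id))
  list(samples = samples, universe = universe, expr = expr)
}

test_that("enrichment p-values equal exact hypergeometric tail sums", {
  fx <- fisher_fixture()
  # the (8, 2, 12, 78) contingency table: universe 100, targets 20, DEGs 10
  deg <- fx$universe[1:10]
  targets <- fx$universe[c(1:8, 11:22)]
  res <- enrich_tf_targets(deg, list(TF1 = targets), fx$universe, fx$expr,
                           fx$samples, "B")
  expect_equal(res$result$overlap, 8L)
  expect_equal(res$result$p_value,
               brute_hyper_tail(8, 20, 100, 10), tolerance = 1e-12)
  expect_true(res$result$kept)
  expect_equal(nrow(res$edges), 8L)
  expect_setequal(res$edges$target, fx$universe[1:8])
})

test_that("enrichment keep rules: disjoint targets, expression floor, empty DEGs", {
  fx <- fisher_fixture()
  deg <- fx$universe[1:10]
  disjoint <- fx$universe[51:70]
  res <- enrich_tf_targets(deg, list(TF1 = disjoint), fx$universe, fx$expr,
                           fx$samples, "B")
  expect_equal(res$result$p_value, 1, tolerance = 1e-12)
  expect_false(res$result$kept)
  # extreme enrichment: DEGs identical to targets, half the universe
  half <- fx$universe[1:50]
  res2 <- enrich_tf_targets(half, list(TF1 = half), fx$universe, fx$expr,
                            fx$samples, "B")
  expect_lt(res2$result$p_value, 1e-10)
  expect_true(res2$result$kept)
  # same overlap but a silent TF fails the expression floor
  expr_low <- fx$expr
  expr_low["TF1", fx$samples$group == "B"] <- 0
  res3 <- enrich_tf_targets(half, list(TF1 = half), fx$universe, expr_low,
                            fx$samples, "B")
  expect_false(res3$result$kept)
  expect_equal(nrow(res3$edges), 0L)
  # empty DEG list gives an empty result
  res4 <- enrich_tf_targets(character(0), list(TF1 = half), fx$universe,
                            fx$expr, fx$samples, "B")
  expect_equal(nrow(res4$result), 0L)
})

test_that("curated-table lookup filters by TF and universe and deduplicates", {
  tab <- tibble::tibble(
    regulator = c("TF1", "TF1", "TF2", "TF3", "TF1"),
    target = c("G1", "G1", "G2", "G3", "OUT"),
    source = "regnet"
  )
  ed <- regnet_lookup(c("TF1", "TF2"), tab, c("G1", "G2", "G3"))
  expect_equal(nrow(ed), 2L)  # dup collapsed, TF3 and OUT excluded
  expect_setequal(paste(ed$regulator, ed$target), c("TF1 G1", "TF2 G2"))
  expect_equal(nrow(regnet_lookup("TFX", tab, c("G1"))), 0L)
})

test_that("network merge deduplicates across sources and directedness", {
  wg <- tibble::tibble(gene_a = c("B2", "C1"), gene_b = c("A1", "C2"),
                       weight = c(0.3, 0.2))
  ch <- tibble::tibble(regulator = c("A1", "D1"), target = c("B2", "D2"),
                       source = "chea")
  rn <- tibble::tibble(regulator = c("A1", "E1"), target = c("B2", "E2"),
                       source = "regnet")
  net <- merge_networks(wg, ch, rn, tf_list = c("A1", "D1", "E1"))
  # A1-B2 appears in all three sources and collapses onto the undirected edge
  e <- net$edges[net$edges$from == "A1" & net$edges$to == "B2", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$sources, "chea+regnet+wgcna")
  expect_false(e$directed)
  expect_equal(e$weight, 0.3)
  expect_equal(nrow(net$edges), 4L)
  # additivity for disjoint inputs
  wg2 <- tibble::tibble(gene_a = paste0("x", 1:3), gene_b = paste0("y", 1:3),
                        weight = 0.1)
  ch2 <- tibble::tibble(regulator = paste0("p", 1:4),
                        target = paste0("q", 1:4), source = "chea")
  rn2 <- tibble::tibble(regulator = paste0("u", 1:5),
                        target = paste0("v", 1:5), source = "regnet")
  expect_equal(nrow(merge_networks(wg2, ch2, rn2)$edges), 12L)
  # order invariance
  net_perm <- merge_networks(wg[2:1, ], ch[2:1, ], rn[2:1, ],
                             tf_list = c("A1", "D1", "E1"))
  expect_identical(net$edges, net_perm$edges)
  expect_identical(net$nodes, net_perm$nodes)
  # every edge carries at least one source tag
  expect_true(all(nzchar(net$edges$sources)))
})

test_that("TF projection keeps TF-TF edges and the full-network degree", {
  # star TF: 10 gene targets plus 1 TF target
  ch <- tibble::tibble(regulator = "HUB",
                       target = c(sprintf("G%02d", 1:10), "TF2"),
                       source = "chea")
  net <- merge_networks(NULL, ch, NULL, tf_list = c("HUB", "TF2"))
  proj <- tf_projection(net, c("HUB", "TF2"))
  expect_equal(nrow(proj$edges), 1L)
  expect_equal(proj$nodes$full_degree[proj$nodes$node == "HUB"], 11L)
  # idempotence
  proj2 <- tf_projection(proj, c("HUB", "TF2"))
  expect_identical(proj2$edges, proj$edges)
  expect_setequal(proj2$nodes$node, proj$nodes$node)
  # no TF-TF edges: empty edge set but TF nodes retained
  ch_only_genes <- ch[1:10, ]
  net2 <- merge_networks(NULL, ch_only_genes, NULL, tf_list = "HUB")
  proj3 <- tf_projection(net2, "HUB")
  expect_equal(nrow(proj3$edges), 0L)
  expect_identical(proj3$nodes$node, "HUB")
  expect_equal(proj3$nodes$full_degree, 10L)
  # full_degree matches an independent incident-edge recount
  recount <- sum(net$edges$from == "HUB") + sum(net$edges$to == "HUB")
  expect_equal(proj$nodes$full_degree[proj$nodes$node == "HUB"], recount)
})

test_that("expression-breadth classes cover all four outcomes", {
  mk_de <- function(sig) tibble::tibble(gene = "TF1", significant = sig)
  groups <- c("B", "T", "NK", "ILC", "DC")
  de_one <- stats::setNames(lapply(groups, function(g) mk_de(g == "B")), groups)
  expect_equal(classify_expression_breadth(de_one, "TF1"), "specific")
  de_all <- stats::setNames(lapply(groups, function(g) mk_de(TRUE)), groups)
  expect_equal(classify_expression_breadth(de_all, "TF1"), "general")
  de_multi <- stats::setNames(
    lapply(groups, function(g) mk_de(g %in% c("ILC", "NK", "DC"))), groups)
  expect_equal(classify_expression_breadth(de_multi, "TF1"), "multi-group")
  de_none <- stats::setNames(lapply(groups, function(g) mk_de(FALSE)), groups)
  expect_equal(classify_expression_breadth(de_none, "TF1"), "none")
})

test_that("interactor OCR annotation averages per group with absent genes as 0", {
  ch <- tibble::tibble(regulator = "TF1", target = c("G1", "G2"),
                       source = "chea")
  net <- merge_networks(NULL, ch, NULL, tf_list = "TF1")
  acc <- tibble::tibble(
    gene = c("G1", "G2", "G1", "G2"),
    group = c("B", "B", "T", "T"),
    ocr_activity = c(4, 8, 7, 7)
  )
  ann <- annotate_ocr(net, acc)
  expect_equal(ann$mean_interactor_ocr[ann$group == "B"], 6)
  expect_equal(ann$mean_interactor_ocr[ann$group == "T"], 7)
  # single interactor passes its score through
  net1 <- merge_networks(NULL, ch[1, ], NULL, tf_list = "TF1")
  ann1 <- annotate_ocr(net1, acc)
  expect_equal(ann1$mean_interactor_ocr[ann1$group == "B"], 4)
  # interactors without peaks contribute zero to the mean
  acc_missing <- acc[acc$gene == "G1", ]
  ann2 <- annotate_ocr(net, acc_missing)
  expect_equal(ann2$mean_interactor_ocr[ann2$group == "B"], 2)  # (4 + 0) / 2
  # a TF with no interactors is annotated all-zero with a message
  net3 <- structure(list(
    nodes = tibble::tibble(node = "LONER", is_tf = TRUE),
    edges = net$edges[0, ]), class = "regulatory_network")
  expect_message(ann3 <- annotate_ocr(net3, acc), "no interactors")
  expect_true(all(ann3$mean_interactor_ocr == 0))
})

test_that("enrichment recovers planted TFs and rejects decoys on synthetic truth", {
  cfg <- small_sim_config(seed = 19L)
  cfg$db_false_positive_rate <- 0
  cfg$db_false_negative_rate <- 0
  sim <- generate_counts(cfg)
  db <- generate_tf_target_db(sim$truth, cfg)
  filtered <- filter_genes(sim$counts)
  expr <- normalize_log2cpm(filtered)
  universe <- rownames(filtered)
  gst <- sim$truth$group_specific_tfs
  decoy_kept <- c()
  for (g in names(gst)[lengths(gst) > 0]) {
    de <- differential_expression(filtered, sim$samples, g, "Stem",
                                  sim$truth$tfs, expr = expr)
    res <- enrich_tf_targets(de$gene[de$significant], db$chea, universe,
                             expr, sim$samples, g)$result
    expect_true(all(res$kept[match(gst[[g]], res$tf)]))
    decoy_kept <- c(decoy_kept, res$kept[res$tf %in% sim$truth$decoy_tfs])
  }
  expect_lte(mean(decoy_kept), 0.05)
})
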