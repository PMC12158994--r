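test_that("signed adjacency follows its closed form", {
  # three genes engineered for exact correlations +1, -1, 0
  expr <- rbind(
    A = c(1, 2, 3, 4),
    B = c(2, 4, 6, 8),    # cor(A, B) = 1
    C = c(4, 3, 2, 1),    # cor(A, C) = -1
    D = c(1, -1, -1, 1)   # cor(A, D) = 0
  )
  colnames(expr) <- paste0("s", 1:4)
  a <- signed_adjacency(expr, 16)
  expect_equal(a["A", "B"], 1)
  expect_equal(a["A", "C"], 0)
  expect_equal(a["A", "D"], 0.5^16, tolerance = 1e-12)
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 4))
  expect_error(signed_adjacency(rbind(expr, E = rep(2, 4)), 16), "constant")
})

test_that("TOM matches a brute-force triple loop and its degenerate forms", {
  # 2-gene network: TOM equals the adjacency off-diagonal
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a2)["x", "y"], 0.3, tolerance = 1e-12)
  # identity adjacency maps to identity TOM
  id <- diag(5)
  dimnames(id) <- list(paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(tom_similarity(id), id)
  set.seed(11)
  a <- rand_adjacency(6)
  expect_equal(tom_similarity(a), brute_tom(a), tolerance = 1e-12)
  tom <- tom_similarity(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("scale-free scan behaves monotonically and recommends a sane power", {
  expr <- two_module_expr(n_per = 40, n_samples = 24, seed = 5)
  fit <- scale_free_fit(expr, candidate_powers = c(2, 4, 8, 12, 16))
  expect_true(all(diff(fit$mean_connectivity) < 0))
  expect_true(all(fit$r_squared >= 0 & fit$r_squared <= 1))
  expect_lte(attr(fit, "recommended_power"), 16)
  # constant gene excluded with a warning, not an error
  expr2 <- rbind(expr, CONST = rep(1, ncol(expr)))
  expect_warning(scale_free_fit(expr2, candidate_powers = c(2, 6)),
                 "constant")
})

test_that("module detection recovers two planted modules exactly", {
  expr <- two_module_expr(n_per = 30, n_samples = 20, noise = 0.1)
  tom <- tom_similarity(signed_adjacency(expr, 6))
  params <- coexpression_params(soft_power = 6, min_module_size = 20)
  mods <- detect_modules(tom, params, expr)
  truth <- rep(1:2, each = 30)
  expect_equal(mclust::adjustedRandIndex(truth, mods), 1)
  expect_equal(length(unique(mods)), 2L)
})

test_that("degenerate and monotone deep-split behaviour", {
  expr <- two_module_expr(n_per = 10, n_samples = 12, noise = 0.3, seed = 2)
  tom <- tom_similarity(signed_adjacency(expr, 6))
  # impossible module size: everything unassigned, no crash
  params_big <- coexpression_params(soft_power = 6, min_module_size = 1000)
  expect_message(m0 <- detect_modules(tom, params_big, expr), "unassigned")
  expect_true(all(m0 == 0))
  # deeper split never yields fewer raw clusters
  raw_clusters <- vapply(c(0L, 3L), function(ds) {
    p <- coexpression_params(soft_power = 6, min_module_size = 5,
                             deep_split = ds)
    attr(detect_modules(tom, p, expr), "n_raw_clusters")
  }, 0L)
  expect_gte(raw_clusters[2], raw_clusters[1])
})

test_that("eigengenes, MM and GS obey their defining identities", {
  set.seed(33)
  n_s <- 24
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:n_s),
    group = rep(c("B", "T", "Stem"), each = n_s / 3),
    subgroup = group
  )
  # module 1 follows the B indicator, module 2 is pure noise structure
  b_ind <- as.numeric(samples$group == "B")
  expr <- rbind(
    t(replicate(20, 5 * b_ind + stats::rnorm(n_s, sd = 0.2))),
    t(replicate(20, stats::rnorm(n_s)))
  )
  dimnames(expr) <- list(sprintf("G%02d", 1:40), samples$sample_id)
  assignment <- stats::setNames(rep(1:2, each = 20), rownames(expr))
  me <- module_eigengene(expr, assignment)
  expect_equal(unname(colSums(me^2)), c(1, 1), tolerance = 1e-12)
  mtc <- module_trait_correlation(me, samples)
  expect_equal(unname(colnames(mtc$cor)[which.max(mtc$cor["ME1", ])]), "B")
  expect_true(all(abs(mtc$cor) <= 1))
  mm_gs <- module_membership(expr, me, assignment, samples)
  expect_true(all(abs(mm_gs$mm) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(abs(mm_gs$gs_B) <= 1 + 1e-12))
  # genes of a coherent module have high positive MM
  expect_true(all(mm_gs$mm[mm_gs$module == 1] > 0.9))
  # a module of identical genes has MM exactly 1
  ident <- matrix(rep(stats::rnorm(n_s), 3), nrow = 3, byrow = TRUE,
                  dimnames = list(c("I1", "I2", "I3"), samples$sample_id))
  a2 <- stats::setNames(rep(1L, 3), rownames(ident))
  me2 <- module_eigengene(ident, a2)
  mm2 <- module_membership(ident, me2, a2, samples)
  expect_equal(mm2$mm, rep(1, 3), tolerance = 1e-9)
})

test_that("edge extraction honours both thresholds and the degree contract", {
  genes <- c("TF1", "TF2", "G1", "G2")
  tom <- diag(4)
  dimnames(tom) <- list(genes, genes)
  tom["TF1", "G1"] <- tom["G1", "TF1"] <- 0.030  # TF edge, kept
  tom["TF1", "G2"] <- tom["G2", "TF1"] <- 0.020  # boundary: >= 0.02 kept
  tom["TF2", "G1"] <- tom["G1", "TF2"] <- 0.019  # below TF threshold
  tom["G1", "G2"] <- tom["G2", "G1"] <- 0.015    # non-TF pair
  assignment <- stats::setNames(c(1L, 1L, 1L, 2L), genes)
  params <- coexpression_params()
  ed <- extract_module_edges(tom, assignment, params, c("TF1", "TF2"))
  # general network: strict > 0.01 keeps all four marked pairs
  expect_equal(nrow(ed$general), 4L)
  # TF-centric network: exactly the two TF1 edges survive
  expect_equal(nrow(ed$tf), 2L)
  expect_setequal(ed$tf$gene_b, c("G1", "G2"))
  expect_equal(unname(ed$tf_degree["TF1"]), 2L)
  expect_equal(unname(ed$tf_degree["TF2"]), 0L)
  # degree equals the TF's row count in the exported edge table
  expect_equal(unname(ed$tf_degree["TF1"]),
               sum(ed$tf$gene_a == "TF1" | ed$tf$gene_b == "TF1"))
  # threshold limits
  p1 <- coexpression_params(edge_weight_threshold = 0.9999,
                            tf_edge_threshold = 0.9999)
  expect_equal(nrow(extract_module_edges(tom, assignment, p1,
                                         c("TF1", "TF2"))$general), 0L)
  p0 <- coexpression_params(edge_weight_threshold = 1e-9)
  expect_equal(nrow(extract_module_edges(tom, assignment, p0,
                                         character(0))$general),
               choose(4, 2) - 2L)  # all pairs with nonzero TOM
})
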