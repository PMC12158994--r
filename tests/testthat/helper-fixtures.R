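# Shared fixtures and independent oracles. Oracles are deliberately naive
# (triple loops, factorial sums, step-up enumeration) and never call the
# implementation paths they check.

# random symmetric adjacency in [0,1] with unit diagonal
rand_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# brute-force topological overlap by triple loop
brute_tom <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- adj[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + adj[i, u] * adj[u, j]
      }
      ki <- sum(adj[i, -i])
      kj <- sum(adj[j, -j])
      out[i, j] <- num / (min(ki, kj) + 1 - adj[i, j])
    }
  }
  dimnames(out) <- dimnames(adj)
  out
}

# hypergeometric upper-tail P(X >= ov) by explicit factorial sums
brute_hyper_tail <- function(ov, set_size, universe, deg_count) {
  i <- ov:min(set_size, deg_count)
  if (ov > min(set_size, deg_count)) return(0)
  sum(exp(lchoose(set_size, i) + lchoose(universe - set_size, deg_count - i) -
            lchoose(universe, deg_count)))
}

# Benjamini-Hochberg by literal step-up enumeration
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# expression matrix with two perfectly separated planted modules:
# each module follows its own latent factor plus small iid noise
two_module_expr <- function(n_per = 30, n_samples = 20, noise = 0.1,
                            seed = 7) {
  set.seed(seed)
  z1 <- stats::rnorm(n_samples)
  z2 <- stats::rnorm(n_samples)
  x <- rbind(
    t(replicate(n_per, z1 + stats::rnorm(n_samples, sd = noise))),
    t(replicate(n_per, z2 + stats::rnorm(n_samples, sd = noise)))
  )
  dimnames(x) <- list(sprintf("G%03d", seq_len(2 * n_per)),
                      sprintf("S%02d", seq_len(n_samples)))
  x
}

# small simulated study shared by several pipeline-level tests
small_sim_config <- function(seed = 9L) {
  sim_config(
    n_genes = 300L, n_tfs = 30L,
    module_specs = data.frame(size = c(60L, 60L),
                              driver_group = c("B", "T"),
                              latent_strength = c(0.8, 0.8)),
    replicates_per_group = 5L,
    seed = seed
  )
}

toy_counts_path <- function() {
  system.file("extdata", "toy_counts.tsv", package = "hemaTFnet",
              mustWork = TRUE)
}
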