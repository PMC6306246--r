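# Shared fixtures: all inputs are generated in code at test time.

# Small well-separated 3-type dataset reused across clustering tests.
three_type_sim <- function(seed = 7, cells = 50, genes = 2000) {
  cfg <- simulation_config(n_types = 3, cells_per_type = cells,
                           nuclei_per_type = 5, n_genes = genes, seed = seed)
  simulate_dataset(cfg)
}

# Single-type (structureless) dataset for null behavior.
noise_sim <- function(seed = 3, cells = 60, genes = 1000) {
  cfg <- simulation_config(n_types = 1, cells_per_type = cells,
                           nuclei_per_type = 5, n_genes = genes,
                           marker_genes_per_type = 0, seed = seed)
  simulate_dataset(cfg)
}

# Tiny deterministic two-layer matrix for I/O and CPM tests.
toy_matrix <- function(n_genes = 5, n_samples = 3, seed = 11) {
  set.seed(seed)
  e <- matrix(rpois(n_genes * n_samples, 10), n_genes, n_samples)
  i <- matrix(rpois(n_genes * n_samples, 4), n_genes, n_samples)
  expression_matrix(e, i,
                    genes = paste0("g", seq_len(n_genes)),
                    samples = paste0("s", seq_len(n_samples)))
}

# Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  r <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- r * c / choose(n, 2)
  (s - e) / ((r + c) / 2 - e)
}
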