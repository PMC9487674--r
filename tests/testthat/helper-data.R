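# small in-code fixtures shared across test files

# tiny deterministic dataset: `g` genes, `s` samples x `cps` cells
tiny_sim <- function(g = 100, s = 6, cps = 30, n_de = 10, theta = 1,
                     phi = 0.2, seed = 42, dist = "poisson") {
  simulate_dataset(sim_config(
    n_samples_total = s, avg_cells_per_sample = cps,
    cell_count_distribution = dist,
    cell_overdispersion = phi, sample_overdispersion = theta,
    n_genes = g, n_de_genes = n_de, seed = seed
  ))
}

# hand-built cell_counts: counts matrix with explicit sample/condition maps
manual_counts <- function(counts, cell_sample, conditions) {
  cell_counts(counts, cell_sample, conditions)
}

# exact two-sided rank-sum p by complete enumeration of group assignments
exact_ranksum_p <- function(x, in_a) {
  n <- length(x); n1 <- sum(in_a)
  r <- rank(x)
  obs <- abs(sum(r[in_a]) - n1 * (n + 1) / 2)
  combos <- utils::combn(n, n1)
  stats_all <- apply(combos, 2, function(idx) {
    abs(sum(r[idx]) - n1 * (n + 1) / 2)
  })
  mean(stats_all >= obs - 1e-12)
}
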