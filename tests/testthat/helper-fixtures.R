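# Shared fixtures, all generated in code.

write_edge_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Three-edge toy network: r1 -> g1 (+), r1 -> g2 (-), r2 -> g2 (+).
tiny_net <- function() {
  read_network(write_edge_file(c("r1\tg1\t+", "r1\tg2\t-", "r2\tg2\t+")))
}

# Small signal-bearing study for fast unit tests.
small_spec <- function(seed, ...) {
  args <- list(num_genes = 300, num_regulators = 20, edges_per_regulator = 8,
               num_active_regulators = 3, effect_size = 3,
               within_group_correlation = 0.1, noise_sd = 1,
               n_samples = 100, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

small_sim <- function(seed, ...) {
  spec <- small_spec(seed, ...)
  simulate_dataset(simulate_network(spec), spec)
}

fast_control <- function(seed = NULL, ...) {
  grrann_control(max_epochs = 300, tol = 1e-6, seed = seed, ...)
}

# Zero-initialized weight list shaped like an architecture.
zero_weights <- function(arch) {
  list(W1 = arch$mask * 0, b1 = rep(0, nrow(arch$mask)),
       W2 = rep(0, nrow(arch$mask)), b2 = 0)
}
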