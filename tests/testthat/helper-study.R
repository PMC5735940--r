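# Reference study conditions shared by the acceptance-level tests: the
# generator defaults (50 regulators, 5 active, effect 3 sd, n = 200, genes
# outnumbering samples), a fixed optimizer budget, and the penalty level
# selected once on the reference dataset by the package's own lambda
# protocol. Expensive shared quantities are computed once per session.

study_control <- function(seed = NULL) {
  grrann_control(max_epochs = 500, tol = 1e-6, seed = seed)
}

study_sim <- function(seed, effect_size = 3) {
  spec <- simulation_spec(effect_size = effect_size, seed = seed)
  simulate_dataset(simulate_network(spec), spec)
}

.study_cache <- new.env(parent = emptyenv())

study_reference <- function() {
  if (is.null(.study_cache$ref)) {
    sim <- study_sim(101)
    .study_cache$ref <- list(sim = sim,
                             arch = build_architecture(sim$network))
  }
  .study_cache$ref
}

study_lambda_search <- function() {
  if (is.null(.study_cache$ls)) {
    ref <- study_reference()
    .study_cache$ls <- lambda_search(ref$sim$x, ref$sim$y, ref$arch,
                                     grid_size = 6, k = 5, seed = 201,
                                     control = study_control())
  }
  .study_cache$ls
}

study_lambda <- function() study_lambda_search()$best_lambda
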