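#' Specify a synthetic study design
#'
#' Parameters of the synthetic benchmark: a bipartite regulator-to-gene
#' network, latent standard-normal regulator activities, a subset of "active"
#' regulators whose activity is shifted by `effect_size` (in activity-sd
#' units) in class-1 samples, and gene expression formed as the signed,
#' \eqn{\sqrt{c}}-scaled sum of incoming regulator activities plus
#' idiosyncratic Gaussian noise — so genes sharing an active regulator are
#' group-correlated and differentially expressed, the regime the
#' group-penalized network model targets.
#'
#' Defaults describe the reference study design used throughout the package
#' tests: 50 regulators over a 1500-gene universe with 15 targets each
#' (roughly 600 genes end up connected, so measured genes outnumber samples,
#' the regime of transcriptomic cohorts), 5 active regulators, a strong
#' latent effect (3 sd), weak per-gene loading (`within_group_correlation`
#' 0.05) over unit noise — individual genes are weak markers and reliable
#' classification requires aggregating each regulator's gene set — and 200
#' balanced samples.
#'
#' @param num_genes,num_regulators Network size.
#' @param edges_per_regulator Distinct target genes per regulator.
#' @param num_active_regulators How many regulators carry the class signal.
#' @param effect_size Activity shift of active regulators in class 1, in sd
#'   units; 0 gives label-independent expression (a null dataset).
#' @param within_group_correlation Scale \eqn{c \in [0,1)} of the shared
#'   regulator-driven variance component.
#' @param noise_sd Idiosyncratic per-gene noise sd.
#' @param n_samples Number of samples.
#' @param class_balance P(label = 1).
#' @param seed Integer seed; identical spec + seed gives byte-identical data.
#' @return A validated list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(num_genes = 1500, num_regulators = 50,
                            edges_per_regulator = 15,
                            num_active_regulators = 5, effect_size = 3,
                            within_group_correlation = 0.05, noise_sd = 1,
                            n_samples = 200, class_balance = 0.5,
                            seed = NULL) {
  spec <- list(num_genes = as.integer(num_genes),
               num_regulators = as.integer(num_regulators),
               edges_per_regulator = as.integer(edges_per_regulator),
               num_active_regulators = as.integer(num_active_regulators),
               effect_size = effect_size,
               within_group_correlation = within_group_correlation,
               noise_sd = noise_sd, n_samples = as.integer(n_samples),
               class_balance = class_balance, seed = seed)
  stopifnot(spec$num_genes >= 1, spec$num_regulators >= 1,
            spec$edges_per_regulator >= 1,
            spec$num_active_regulators >= 0,
            spec$num_active_regulators <= spec$num_regulators,
            spec$effect_size >= 0,
            spec$within_group_correlation >= 0,
            spec$within_group_correlation < 1,
            spec$noise_sd > 0, spec$n_samples >= 2,
            spec$class_balance > 0, spec$class_balance < 1)
  if (spec$edges_per_regulator > spec$num_genes)
    stop("edges_per_regulator exceeds num_genes")
  structure(spec, class = "simulation_spec")
}

id_pad <- function(prefix, i, n)
  sprintf("%s%0*d", prefix, max(2L, nchar(n)), i)

#' Simulate a bipartite regulatory network
#'
#' Each regulator is assigned `edges_per_regulator` distinct target genes
#' drawn uniformly (targets may overlap across regulators, emulating
#' overlapping co-regulated gene sets); edge signs are uniform over
#' activating/repressing.
#'
#' @param spec A [simulation_spec()].
#' @return A `grn` object with `num_regulators * edges_per_regulator` edges.
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- id_pad("g", seq_len(spec$num_genes), spec$num_genes)
  regs <- id_pad("r", seq_len(spec$num_regulators), spec$num_regulators)
  with_seed(spec$seed, {
    regulator <- rep(regs, each = spec$edges_per_regulator)
    gene <- unlist(lapply(regs, function(r)
      genes[sample.int(spec$num_genes, spec$edges_per_regulator)]))
    sign <- sample(c("activating", "repressing"), length(gene),
                   replace = TRUE)
    new_grn(regulator, gene, sign)
  })
}

#' Simulate expression and phenotype from a regulatory network
#'
#' Labels are drawn Bernoulli(`class_balance`) (redrawn, up to 100 times, if
#' a single class comes up); per sample, latent regulator activities are
#' standard normal, with `effect_size` added to the activities of the active
#' regulators in class-1 samples; each gene is the sum over its incoming
#' edges of \eqn{\mathrm{sign} \cdot \sqrt{c} \cdot \mathrm{activity}} plus
#' Normal(0, `noise_sd`) noise. With `effect_size = 0` a gene's marginal
#' variance is \eqn{c \cdot \rho^{in}_g + \mathrm{noise\_sd}^2}.
#'
#' @param net A `grn`, normally from [simulate_network()] with the same spec.
#' @param spec A [simulation_spec()].
#' @return A `grrann_sim` list: `x` (n x genes matrix), `y` (named 0/1),
#'   `active_regulators` (ground truth), `activities` (latent n x regulators
#'   matrix), `network`, `spec`.
#' @export
simulate_dataset <- function(net, spec) {
  stopifnot(inherits(net, "grn"), inherits(spec, "simulation_spec"))
  arch <- build_architecture(net)
  R <- length(arch$regulator_index); G <- length(arch$gene_index)
  n <- spec$n_samples
  # independent child stream so dataset draws do not replay network draws
  ds_seed <- if (is.null(spec$seed)) NULL else derive_seeds(spec$seed, 2L)[[2L]]
  with_seed(ds_seed, {
    y <- NULL
    for (try in 1:100) {
      cand <- stats::rbinom(n, 1L, spec$class_balance)
      if (length(unique(cand)) == 2L) { y <- cand; break }
    }
    if (is.null(y)) stop("degenerate labels: one class in 100 redraws")
    active <- sort(sample(arch$regulator_index, spec$num_active_regulators))
    A <- matrix(stats::rnorm(n * R), n, R,
                dimnames = list(NULL, arch$regulator_index))
    A[, active] <- A[, active] + spec$effect_size * y
    loadings <- t(arch$signs) * sqrt(spec$within_group_correlation) # G x R
    x <- A %*% t(loadings) +
      matrix(stats::rnorm(n * G, sd = spec$noise_sd), n, G)
    sample_ids <- id_pad("s", seq_len(n), n)
    dimnames(x) <- list(sample_ids, arch$gene_index)
    structure(list(x = x, y = stats::setNames(y, sample_ids),
                   active_regulators = active, activities = A,
                   network = net, spec = spec),
              class = "grrann_sim")
  })
}

#' @export
print.grrann_sim <- function(x, ...) {
  cat("Synthetic expression study:", nrow(x$x), "samples x", ncol(x$x),
      "genes\n")
  cat("  classes: ", sum(x$y == 0), " / ", sum(x$y == 1),
      "; active regulators: ", paste(x$active_regulators, collapse = ", "),
      "\n", sep = "")
  cat("  effect size", x$spec$effect_size, "sd; group correlation scale",
      x$spec$within_group_correlation, "\n")
  invisible(x)
}

#' Write a simulated study as pipeline input files
#'
#' Emits exactly the formats the pipeline consumes — `network.tsv` (edge
#' list), `expression.tsv` (samples x genes), `labels.tsv` — plus
#' `truth.json` recording the planted active regulators and the spec.
#'
#' @param sim A `grrann_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "grrann_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  write_network(sim$network, paths[["network"]])
  write_expression(sim$x, paths[["expression"]])
  write_labels(sim$y, paths[["labels"]])
  jsonlite::write_json(list(active_regulators = sim$active_regulators,
                            spec = unclass(sim$spec)),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
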