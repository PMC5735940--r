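#' Bootstrap stability ranking of regulators
#'
#' Measures how robustly each hidden unit (regulator) is selected under
#' resampling of the training data: for each run the samples are drawn with
#' replacement, standardized, the model refit, and regulators ranked by the
#' magnitude of their output weight \eqn{|W^{(2)}_i|}. The report counts how
#' often each regulator appears in the top `top_k` of these ranked lists;
#' regulators on the upper quantiles of the frequency distribution are the
#' stable predictors.
#'
#' Only regulators with a nonzero output weight (above `control$zero_eps`)
#' can occupy top-`top_k` slots, so a run with fewer than `top_k` active
#' regulators contributes fewer entries. Ties in magnitude are broken by
#' regulator id (ascending) for determinism. Resamples that miss a class are
#' redrawn (up to 100 times). The penalty level is held fixed across runs
#' (select it once, e.g. with [lambda_search()], before bootstrapping).
#'
#' @param x Raw expression matrix, samples x genes.
#' @param y Binary labels.
#' @param architecture A `grrann_arch`.
#' @param lambda,alpha,variant,control Passed to [grrann()].
#' @param num_runs Number of bootstrap resamples (100 in the reference
#'   protocol).
#' @param top_k List depth that counts as "top" (10 in the reference
#'   protocol).
#' @param quantile_cut Frequency quantile above which a regulator is flagged
#'   `selected`.
#' @param seed Seed; the whole report is a deterministic function of the
#'   inputs and this seed.
#' @return A `grrann_boot` object: `num_runs`, `top_k`, `frequency` (named
#'   count vector over all regulators), `ranked_lists` (per-run ranked
#'   regulator ids), `selected`, `seed`.
#' @export
bootstrap_stability <- function(x, y, architecture, lambda, alpha = 0.5,
                                variant = "grrann",
                                control = grrann_control(), num_runs = 100,
                                top_k = 10, quantile_cut = 0.75,
                                seed = NULL) {
  stopifnot(num_runs >= 1, top_k >= 1,
            quantile_cut > 0, quantile_cut < 1)
  x <- align_genes(x, architecture)
  y <- check_labels(y, nrow(x))
  n <- nrow(x)
  regs <- architecture$regulator_index
  run_seeds <- derive_seeds(seed, 2L * num_runs)
  freq <- stats::setNames(integer(length(regs)), regs)
  ranked_lists <- vector("list", num_runs)
  for (r in seq_len(num_runs)) {
    idx <- NULL
    with_seed(run_seeds[[r]], for (try in 1:100) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[cand])) == 2L) { idx <- cand; break }
    })
    if (is.null(idx))
      stop("persistent single-class resamples after 100 redraws")
    ctl <- control
    ctl$seed <- run_seeds[[num_runs + r]]
    fit <- grrann(standardize(x[idx, , drop = FALSE]), y[idx], architecture,
                  lambda = lambda, alpha = alpha, variant = variant,
                  control = ctl)
    ord <- order(-abs(fit$W2), regs, method = "radix")
    ranked_lists[[r]] <- regs[ord]
    nz <- sum(abs(fit$W2) > control$zero_eps)
    top <- regs[ord][seq_len(min(top_k, nz))]
    freq[top] <- freq[top] + 1L
  }
  cut <- stats::quantile(freq, quantile_cut, names = FALSE)
  structure(list(num_runs = num_runs, top_k = top_k, frequency = freq,
                 ranked_lists = ranked_lists,
                 selected = names(freq)[freq >= cut],
                 quantile_cut = quantile_cut, lambda = lambda, seed = seed),
            class = "grrann_boot")
}

#' @export
print.grrann_boot <- function(x, ...) {
  cat("Bootstrap stability report:", x$num_runs, "runs, top", x$top_k, "\n")
  top <- sort(x$frequency, decreasing = TRUE)
  show <- utils::head(top[top > 0], 10)
  cat("  most frequent regulators:\n")
  if (length(show))
    print(show) else cat("  (no regulator ever active)\n")
  cat("  selected (frequency >=", paste0(x$quantile_cut, "-quantile):"),
      length(x$selected), "regulator(s)\n")
  invisible(x)
}

#' Write a bootstrap frequency table
#'
#' Three-column TSV (`regulator`, `count`, `selected`), sorted by decreasing
#' count then regulator id — the input expected by downstream heat-mapping or
#' gene-set enrichment tools.
#'
#' @param report A `grrann_boot` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_report <- function(report, path) {
  stopifnot(inherits(report, "grrann_boot"))
  ord <- order(-report$frequency, names(report$frequency), method = "radix")
  utils::write.table(
    data.frame(regulator = names(report$frequency)[ord],
               count = as.integer(report$frequency[ord]),
               selected = as.integer(names(report$frequency)[ord] %in%
                                       report$selected)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
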