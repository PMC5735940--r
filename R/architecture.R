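#' Build the sparse network architecture from a regulatory network
#'
#' Converts a `grn` into the connectivity structure of the classifier: input
#' nodes are genes, hidden nodes are regulators, and the binary mask has a 1
#' exactly where the network contains the corresponding regulator-to-gene
#' edge. `rho` holds each regulator's in-degree (number of incoming gene
#' connections); its square root later scales that regulator's group penalty.
#'
#' With `sign_filter` the architecture can be built from activating or
#' repressing edges only; regulators left without edges after filtering are
#' removed, so `rho >= 1` always holds.
#'
#' @param net A `grn` object.
#' @param sign_filter One of `"all"`, `"activating_only"`, `"repressing_only"`.
#' @return A `grrann_arch` object: list with `gene_index` (column order),
#'   `regulator_index` (row order), `mask` (0/1 matrix, regulators x genes),
#'   `signs` (same shape, entries in -1/0/+1; unknown-sign edges are +1 for
#'   simulation purposes) and `rho` (row sums of `mask`).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("r1\tg1\t+", "r1\tg2\t-", "r2\tg2\t+"), tf)
#' arch <- build_architecture(read_network(tf))
#' arch$mask
#' arch$rho
build_architecture <- function(net,
                               sign_filter = c("all", "activating_only",
                                               "repressing_only")) {
  stopifnot(inherits(net, "grn"))
  sign_filter <- match.arg(sign_filter)
  edges <- net$edges
  if (sign_filter == "activating_only")
    edges <- edges[edges$sign == "activating", , drop = FALSE]
  if (sign_filter == "repressing_only")
    edges <- edges[edges$sign == "repressing", , drop = FALSE]
  if (nrow(edges) == 0L) stop("empty architecture after sign filter")

  gene_index <- sort_ids(edges$gene)
  regulator_index <- sort_ids(edges$regulator)
  mask <- matrix(0, length(regulator_index), length(gene_index),
                 dimnames = list(regulator_index, gene_index))
  signs <- mask
  i <- match(edges$regulator, regulator_index)
  j <- match(edges$gene, gene_index)
  mask[cbind(i, j)] <- 1
  signs[cbind(i, j)] <- ifelse(edges$sign == "repressing", -1, 1)
  new_arch(gene_index, regulator_index, mask, signs)
}

new_arch <- function(gene_index, regulator_index, mask, signs = NULL) {
  rho <- as.integer(rowSums(mask))
  names(rho) <- regulator_index
  structure(list(gene_index = gene_index,
                 regulator_index = regulator_index,
                 mask = mask,
                 signs = signs %||% mask,
                 rho = rho),
            class = "grrann_arch")
}

#' @export
print.grrann_arch <- function(x, ...) {
  cat("Network architecture:", length(x$gene_index), "genes ->",
      length(x$regulator_index), "regulators ->", "1 output\n")
  cat("  connections:", sum(x$mask), " (density ",
      signif(mean(x$mask), 3), ")\n", sep = "")
  cat("  in-degree rho: min", min(x$rho), "median", stats::median(x$rho),
      "max", max(x$rho), "\n")
  if (any(x$rho == 0))
    cat("  note:", sum(x$rho == 0), "regulator(s) with no connections",
        "(randomized architecture)\n")
  invisible(x)
}

#' Randomize the input-to-hidden connections (ablation architecture)
#'
#' Keeps the gene and regulator node sets fixed but redraws the same total
#' number of connections uniformly at random among all (regulator, gene)
#' pairs, without duplicates. This destroys the biological grouping while
#' preserving layer sizes and connection count, providing the negative control
#' against which the value of the true regulatory topology is measured.
#' Regulators that end up with no connections are retained (node sets must be
#' identical) and listed in the `zero_rho` field.
#'
#' By default the redraw is fully uniform; `degree_preserving = TRUE` instead
#' redraws each regulator's target genes separately so per-regulator
#' in-degrees (`rho`) are conserved, for sensitivity analysis.
#'
#' The number of redrawn edges that coincide with original edges is attached
#' as attribute `"overlap"` (shuffled networks retain some true edges by
#' chance).
#'
#' @param arch A `grrann_arch`.
#' @param seed Integer seed; the same seed reproduces the same shuffle.
#' @param degree_preserving Conserve per-regulator in-degrees.
#' @return A `grrann_arch` with the same node indices and edge count.
#' @export
randomize_architecture <- function(arch, seed, degree_preserving = FALSE) {
  stopifnot(inherits(arch, "grrann_arch"))
  R <- length(arch$regulator_index); G <- length(arch$gene_index)
  n_edges <- sum(arch$mask)
  mask <- matrix(0, R, G, dimnames = dimnames(arch$mask))
  with_seed(seed, {
    if (degree_preserving) {
      for (i in seq_len(R)) {
        k <- sum(arch$mask[i, ])
        if (k > 0) mask[i, sample.int(G, k)] <- 1
      }
    } else {
      mask[sample.int(R * G, n_edges)] <- 1
    }
  })
  out <- new_arch(arch$gene_index, arch$regulator_index, mask)
  out$zero_rho <- arch$regulator_index[out$rho == 0]
  attr(out, "overlap") <- sum(mask == 1 & arch$mask == 1)
  out
}

#' Serialize / restore an architecture descriptor
#'
#' The JSON descriptor stores the gene and regulator orderings plus the edge
#' list; the mask is reconstructed on load.
#'
#' @param arch A `grrann_arch`.
#' @param path JSON file path.
#' @return `write_architecture()` returns `path` invisibly;
#'   `read_architecture()` returns the `grrann_arch`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "grrann_arch"))
  idx <- which(arch$mask == 1, arr.ind = TRUE)
  jsonlite::write_json(
    list(gene_index = arch$gene_index,
         regulator_index = arch$regulator_index,
         edges = data.frame(regulator = arch$regulator_index[idx[, 1]],
                            gene = arch$gene_index[idx[, 2]],
                            sign = arch$signs[idx])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- matrix(0, length(d$regulator_index), length(d$gene_index),
                 dimnames = list(d$regulator_index, d$gene_index))
  signs <- mask
  i <- match(d$edges$regulator, d$regulator_index)
  j <- match(d$edges$gene, d$gene_index)
  mask[cbind(i, j)] <- 1
  signs[cbind(i, j)] <- d$edges$sign
  new_arch(d$gene_index, d$regulator_index, mask, signs)
}
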