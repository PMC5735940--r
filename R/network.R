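#' Read a regulator-to-gene edge list
#'
#' Parses a tab-separated edge list describing a signed bipartite gene
#' regulatory network. Each row is `regulator<TAB>gene<TAB>sign` with sign
#' tokens `+` (activating), `-` (repressing) or `0` (unknown); a two-column
#' file implies every sign is unknown. A header row is skipped automatically
#' when the first row has three or more columns and its third token is not one
#' of `+`, `-`, `0`.
#'
#' Identifiers are whitespace-trimmed and matched exactly (case-preserving).
#' Duplicate (regulator, gene) rows collapse to the first-seen sign with a
#' warning; a self-referential edge (regulator id equal to gene id) is an
#' error. Regulator and gene orderings are lexicographic so repeated parses of
#' the same file are identical.
#'
#' @param path Path to the edge-list file.
#' @param sep Field separator, default tab.
#' @return A `grn` object: a list with `regulators` and `genes` (sorted
#'   character vectors) and `edges`, a data frame with columns `regulator`,
#'   `gene` and `sign` (factor with levels `activating`, `repressing`,
#'   `unknown`), sorted by (regulator, gene).
#' @seealso [write_network()], [intersect_network()], [build_architecture()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("r1\tg1\t+", "r1\tg2\t-", "r2\tg2\t+"), tf)
#' net <- read_network(tf)
#' net
read_network <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) stop("empty network: ", path)

  split_row <- function(line) trimws(strsplit(line, sep, fixed = TRUE)[[1L]])
  first <- split_row(lines[lines_keep[1L]])
  has_header <- length(first) >= 3L && !(first[3L] %in% c("+", "-", "0"))
  if (has_header) lines_keep <- lines_keep[-1L]
  if (length(lines_keep) == 0L) stop("empty network: ", path)

  n <- length(lines_keep)
  regulator <- character(n); gene <- character(n); sign <- character(n)
  for (k in seq_len(n)) {
    i <- lines_keep[k]
    tok <- split_row(lines[i])
    if (length(tok) < 2L || !nzchar(tok[1L]) || !nzchar(tok[2L]))
      stop("malformed edge row at line ", i, ": expected at least 2 columns")
    s <- if (length(tok) >= 3L && nzchar(tok[3L])) tok[3L] else "0"
    if (!s %in% c("+", "-", "0"))
      stop("unrecognized sign token '", s, "' at line ", i)
    regulator[k] <- tok[1L]; gene[k] <- tok[2L]; sign[k] <- s
  }
  new_grn(regulator, gene,
          c("+" = "activating", "-" = "repressing", "0" = "unknown")[sign])
}

sign_levels <- c("activating", "repressing", "unknown")

# Construct a validated grn from parallel edge vectors (first-seen dedupe).
new_grn <- function(regulator, gene, sign) {
  if (any(regulator == gene))
    stop("self-referential edge(s): ",
         paste(unique(regulator[regulator == gene]), collapse = ", "))
  key <- paste(regulator, gene, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate (regulator, gene) row(s) collapsed to the ",
            "first-seen sign")
    regulator <- regulator[!dup]; gene <- gene[!dup]; sign <- sign[!dup]
  }
  edges <- data.frame(regulator = regulator, gene = gene,
                      sign = factor(sign, levels = sign_levels),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$gene, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(regulators = sort_ids(edges$regulator),
                 genes = sort_ids(edges$gene),
                 edges = edges),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Gene regulatory network:", length(x$regulators), "regulators,",
      length(x$genes), "genes,", nrow(x$edges), "edges\n")
  tab <- table(x$edges$sign)
  cat("  signs:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a network as a canonical sorted edge list
#'
#' Serializes a `grn` as a three-column TSV (`regulator`, `gene`, sign token in
#' `+`/`-`/`0`), sorted by (regulator, gene). `read_network()` on the output
#' reproduces the object exactly.
#'
#' @param net A `grn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  tok <- c(activating = "+", repressing = "-", unknown = "0")
  writeLines(paste(net$edges$regulator, net$edges$gene,
                   tok[as.character(net$edges$sign)], sep = "\t"),
             path)
  invisible(path)
}

#' Restrict a network to the genes measured in a dataset
#'
#' Drops edges whose target gene is not among `measured`, then removes
#' regulators left with no edges. Counts of dropped genes and regulators are
#' reported via `message()` and attached as the `"dropped"` attribute.
#'
#' @param net A `grn` object.
#' @param measured Character vector of measured gene identifiers.
#' @return The restricted `grn`.
#' @export
intersect_network <- function(net, measured) {
  stopifnot(inherits(net, "grn"))
  if (length(measured) == 0L) stop("`measured` must be non-empty")
  measured <- trimws(as.character(measured))
  keep <- net$edges$gene %in% measured
  if (!any(keep)) stop("no overlap between network and dataset genes")
  edges <- net$edges[keep, , drop = FALSE]
  out <- new_grn(edges$regulator, edges$gene, as.character(edges$sign))
  dropped <- c(genes = length(net$genes) - length(out$genes),
               regulators = length(net$regulators) - length(out$regulators))
  if (any(dropped > 0))
    message("intersect_network: dropped ", dropped[["genes"]], " gene(s) and ",
            dropped[["regulators"]], " regulator(s) not backed by the data")
  attr(out, "dropped") <- dropped
  out
}
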