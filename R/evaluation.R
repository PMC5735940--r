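#' Standardize an expression matrix gene-wise
#'
#' Centers each gene (column) to mean 0 and scales to standard deviation 1,
#' using the population standard deviation (divisor `n`). Constant columns
#' are mapped to all zeros with a warning. Training and test sets must always
#' be standardized independently, each on its own statistics — never with
#' shared or carried-over statistics.
#'
#' @param x Numeric matrix, samples x genes, at least 2 rows.
#' @param ddof Degrees-of-freedom correction for the standard deviation: 0
#'   (population, default) or 1 (sample).
#' @return The standardized matrix, with per-gene statistics attached as
#'   attributes `"center"` and `"scale"`.
#' @export
#' @examples
#' standardize(cbind(g1 = c(1, 2, 3), g2 = c(4, 0, 2)))
standardize <- function(x, ddof = 0) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("standardize: need at least 2 samples")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sd_ <- sqrt(colSums(xc^2) / (n - ddof))
  const <- sd_ == 0
  if (any(const)) {
    warning(sum(const), " constant gene column(s) standardized to all zeros")
    sd_[const] <- 1
    xc[, const] <- 0
  }
  out <- sweep(xc, 2L, sd_, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sd_
  out
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity,
#' \eqn{(\mathrm{TPR} + \mathrm{TNR})/2}; 0.5 for any constant predictor
#' regardless of class imbalance.
#'
#' @param y_true Observed 0/1 labels; both classes must be present.
#' @param y_pred Predicted 0/1 labels.
#' @return A number in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred))
    stop("balanced_accuracy: length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0, 1)))
    stop("balanced_accuracy: labels must be 0/1")
  if (length(unique(y_true)) < 2L)
    stop("balanced_accuracy: y_true contains a single class")
  sens <- mean(y_pred[y_true == 1] == 1)
  spec <- mean(y_pred[y_true == 0] == 0)
  (sens + spec) / 2
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold class proportions track the full data.
stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k)
    stop("class too small for ", k, "-fold stratification")
  fold <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions samples into `k` stratified folds; for each fold the training
#' portion is standardized on its own statistics, the model fit, the held-out
#' portion standardized independently, and balanced accuracy recorded.
#' Reproducible under `seed` (which also derives per-fold initialization
#' seeds).
#'
#' @param x Raw (unstandardized) expression matrix, samples x genes.
#' @param y Binary labels.
#' @param architecture A `grrann_arch`.
#' @param k Number of folds (default 5).
#' @param lambda,alpha,variant,control Passed to [grrann()].
#' @param seed Integer seed for fold assignment and fits.
#' @return A `grrann_cv` object: `fold_accuracies`, `mean_balanced_accuracy`,
#'   per-fold `confusion` counts, the fold assignment and the seed.
#' @export
cv_grrann <- function(x, y, architecture, k = 5, lambda, alpha = 0.5,
                      variant = "grrann", control = grrann_control(),
                      seed = NULL) {
  x <- align_genes(x, architecture)
  y <- check_labels(y, nrow(x))
  fold <- stratified_folds(y, k, seed)
  fit_seeds <- derive_seeds(seed, k)
  acc <- numeric(k)
  confusion <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    ctl <- control; ctl$seed <- fit_seeds[[f]]
    fit <- grrann(standardize(x[tr, , drop = FALSE]), y[tr], architecture,
                  lambda = lambda, alpha = alpha, variant = variant,
                  control = ctl)
    pred <- predict(fit, standardize(x[te, , drop = FALSE]))
    acc[f] <- balanced_accuracy(y[te], pred)
    confusion[[f]] <- c(tp = sum(pred == 1 & y[te] == 1),
                        fp = sum(pred == 1 & y[te] == 0),
                        tn = sum(pred == 0 & y[te] == 0),
                        fn = sum(pred == 0 & y[te] == 1))
  }
  structure(list(fold_accuracies = acc,
                 mean_balanced_accuracy = mean(acc),
                 confusion = confusion, folds = fold, k = k, seed = seed,
                 lambda = lambda, variant = variant),
            class = "grrann_cv")
}

#' @export
print.grrann_cv <- function(x, ...) {
  cat(x$k, "-fold CV (", x$variant, ", lambda = ", format(x$lambda), ")\n",
      sep = "")
  cat("  fold balanced accuracies:",
      paste(round(x$fold_accuracies, 3), collapse = ", "), "\n")
  cat("  mean balanced accuracy:", round(x$mean_balanced_accuracy, 4), "\n")
  invisible(x)
}

#' Train on one cohort, test on an independent cohort
#'
#' Standardizes the training set on its own statistics, fits on all training
#' samples, standardizes the test set independently, and reports test
#' balanced accuracy — the protocol for truly independent train/test cohorts,
#' where CV-to-test accuracy drop measures overfitting.
#'
#' @param x_train,y_train Raw training expression and labels.
#' @param x_test,y_test Raw test expression and labels.
#' @param architecture A `grrann_arch`; intersect both datasets' genes with
#'   the network before calling.
#' @param lambda,alpha,variant,control Passed to [grrann()].
#' @return List with `balanced_accuracy` and the fitted `model`.
#' @export
independent_test <- function(x_train, y_train, x_test, y_test, architecture,
                             lambda, alpha = 0.5, variant = "grrann",
                             control = grrann_control()) {
  fit <- grrann(standardize(align_genes(x_train, architecture)), y_train,
                architecture, lambda = lambda, alpha = alpha,
                variant = variant, control = control)
  pred <- predict(fit, standardize(align_genes(x_test, architecture)))
  list(balanced_accuracy = balanced_accuracy(y_test, pred), model = fit)
}

#' Read an expression matrix or a label file
#'
#' Expression files are TSV (or CSV by extension) with samples in rows, the
#' first column holding sample ids and the header row holding gene ids;
#' `transpose = TRUE` handles genes-in-rows files. Rows or columns containing
#' missing values are rejected. Label files are two-column TSV
#' (sample id, 0/1) without header.
#'
#' @param path Input file.
#' @param transpose Input has genes in rows, samples in columns.
#' @return `read_expression()`: numeric matrix with sample-id rownames and
#'   gene-id colnames. `read_labels()`: named 0/1 vector.
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(d)
  storage.mode(x) <- "double"
  if (transpose) x <- t(x)
  if (anyNA(x))
    stop("expression matrix contains missing values (",
         sum(rowSums(is.na(x)) > 0), " affected row(s))")
  x
}

#' @rdname read_expression
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("label file must have 2 columns (sample id, 0/1)")
  y <- as.numeric(d[[2L]])
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be 0/1")
  stats::setNames(y, trimws(as.character(d[[1L]])))
}

#' Write expression / labels in the formats the package reads
#'
#' @param x Expression matrix (samples x genes) with dimnames.
#' @param y Named 0/1 label vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  d <- data.frame(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                  x, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_labels <- function(y, path) {
  utils::write.table(
    data.frame(names(y) %||% paste0("s", seq_along(y)), as.integer(y)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
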