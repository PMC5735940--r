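#' Fit a network-constrained regularized neural network
#'
#' Trains a single-hidden-layer classifier whose input-to-hidden connections
#' follow a gene regulatory network: hidden unit \eqn{i} (a regulator) sees
#' only its target genes, through the masked weight matrix \eqn{W^{(1)}};
#' hidden activations are ReLU and the single output unit is a sigmoid. The
#' fit minimizes the mean cross-entropy plus the mixed penalty
#' \deqn{g(\alpha,\lambda,W) = \alpha\lambda \|W^{(1)}\|_2^2 +
#'   (1-\alpha)\lambda \sum_i \sqrt{\rho_i}\,|W^{(2)}_i|}
#' where \eqn{\rho_i} is regulator \eqn{i}'s in-degree. The group-lasso term
#' on \eqn{W^{(2)}} shrinks whole regulators: when \eqn{W^{(2)}_i} hits exactly
#' zero the unit's gene set no longer influences the output (group drop-out),
#' while the ridge term spreads weight across the correlated genes of a group.
#'
#' Optimization is full-batch proximal gradient descent with backtracking line
#' search; the \eqn{\ell_1} terms are applied by soft-thresholding, so zeros
#' are exact, and the penalized objective is non-increasing across epochs.
#'
#' Alternative penalties (`variant`) reproduce the ablations of the method:
#' `"half_l2"` ridge on \eqn{W^{(1)}} only (\eqn{\alpha = 1}), `"half_l1"`
#' group lasso on \eqn{W^{(2)}} only (\eqn{\alpha = 0}), `"full_l1"` lasso on
#' both layers, `"full_l2"` ridge on both layers (group ridge on
#' \eqn{W^{(2)}}, \eqn{\sqrt{\rho_i}}-weighted).
#'
#' @param x Numeric matrix, samples x genes, columns aligned to
#'   `architecture$gene_index` (reordered by column name when names are
#'   present). Expected standardized; see [standardize()].
#' @param y Binary labels (0/1 vector, one per row of `x`); both classes must
#'   be present.
#' @param architecture A `grrann_arch` from [build_architecture()].
#' @param lambda Nonnegative penalty level.
#' @param alpha Penalty tradeoff in \[0, 1\]; `alpha = 0.5` balances the ridge
#'   and group-lasso terms.
#' @param variant Penalty variant, see Details.
#' @param control Optimizer settings from [grrann_control()].
#' @return An object of class `"grrann"`: weights (`W1`, `b1`, `W2`, `b2`),
#'   the architecture, penalty settings, per-epoch objective `trace`,
#'   convergence info, training `fitted` probabilities and `dropped` (regulator
#'   ids whose output weight is zero at `zero_eps` resolution).
#' @seealso [predict.grrann()], [cv_grrann()], [lambda_search()],
#'   [bootstrap_stability()]
#' @export
#' @examples
#' sim <- simulate_dataset(simulate_network(simulation_spec(seed = 1)),
#'                         simulation_spec(seed = 1))
#' arch <- build_architecture(sim$network)
#' fit <- grrann(standardize(sim$x), sim$y, arch, lambda = 0.05,
#'               control = grrann_control(seed = 1, max_epochs = 200))
#' fit
grrann <- function(x, y, architecture, lambda, alpha = 0.5,
                   variant = c("grrann", "half_l1", "half_l2", "full_l1",
                               "full_l2"),
                   control = grrann_control()) {
  stopifnot(inherits(architecture, "grrann_arch"))
  variant <- match.arg(variant)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("negative lambda")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  x <- align_genes(x, architecture)
  y <- check_labels(y, nrow(x))
  res <- fit_weights(architecture, x, y, lambda, alpha, variant, control)
  fitted <- nn_forward(res$w, x)$yhat
  structure(list(W1 = res$w$W1, b1 = res$w$b1, W2 = res$w$W2, b2 = res$w$b2,
                 architecture = architecture, lambda = lambda, alpha = alpha,
                 variant = variant, control = control,
                 trace = res$trace, objective = res$objective,
                 epochs = res$epochs, converged = res$converged,
                 fitted = fitted, y = y,
                 dropped = architecture$regulator_index[
                   abs(res$w$W2) <= control$zero_eps],
                 call = match.call()),
            class = "grrann")
}

#' Optimizer and reproducibility settings
#'
#' @param learning_rate Initial proximal-gradient step size; backtracking
#'   halves it whenever the quadratic majorizer is violated.
#' @param max_epochs Maximum number of full-batch proximal steps.
#' @param tol Stop when the penalized objective improves by less than this.
#' @param zero_eps Magnitude below which an output weight counts as zero when
#'   reporting dropped regulators (training itself produces exact zeros).
#' @param seed Integer seed for weight initialization; `NULL` leaves the RNG
#'   state alone.
#' @param squared_l2 Use the squared sum-of-squares ridge term (default); if
#'   `FALSE`, the unsquared Frobenius norm of `W1` is penalized instead.
#' @return A list of class `"grrann_control"`.
#' @export
grrann_control <- function(learning_rate = 0.05, max_epochs = 2000,
                           tol = 1e-7, zero_eps = 1e-8, seed = NULL,
                           squared_l2 = TRUE) {
  stopifnot(learning_rate > 0, max_epochs >= 1, tol >= 0, zero_eps > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 zero_eps = zero_eps, seed = seed, squared_l2 = squared_l2),
            class = "grrann_control")
}

# Align expression columns with the architecture's gene order.
align_genes <- function(x, architecture) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(architecture$gene_index, colnames(x))
    if (length(missing))
      stop("expression matrix lacks architecture gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...")
    x <- x[, architecture$gene_index, drop = FALSE]
  } else if (ncol(x) != length(architecture$gene_index)) {
    stop("dimension mismatch: ", ncol(x), " columns vs ",
         length(architecture$gene_index), " architecture genes")
  }
  storage.mode(x) <- "double"
  x
}

check_labels <- function(y, n) {
  y <- as.numeric(y)
  if (length(y) != n) stop("labels and samples differ in length")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be 0/1")
  y
}

#' @export
print.grrann <- function(x, ...) {
  cat("Network-constrained regularized neural net (", x$variant, ")\n",
      sep = "")
  cat("  ", length(x$architecture$gene_index), " genes -> ",
      length(x$architecture$regulator_index), " regulators -> 1 output; ",
      sum(x$architecture$mask), " connections\n", sep = "")
  cat("  lambda = ", format(x$lambda), ", alpha = ", format(x$alpha), "\n",
      sep = "")
  active <- sum(abs(x$W2) > x$control$zero_eps)
  cat("  active regulators: ", active, " / ", length(x$W2),
      "  (", length(x$dropped), " dropped)\n", sep = "")
  cat("  objective ", format(x$objective, digits = 6), " after ", x$epochs,
      " epochs (", if (x$converged) "converged" else "max epochs", ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.grrann <- function(object, n_top = 10, ...) {
  w2 <- abs(object$W2)
  ord <- order(-w2, object$architecture$regulator_index, method = "radix")
  top <- data.frame(regulator = object$architecture$regulator_index[ord],
                    weight = object$W2[ord],
                    rho = object$architecture$rho[ord],
                    row.names = NULL)[seq_len(min(n_top, length(w2))), ]
  out <- list(fit = object, top = top,
              n_active = sum(w2 > object$control$zero_eps),
              train_accuracy = balanced_accuracy(
                object$y, as.integer(object$fitted >= 0.5)))
  class(out) <- "summary.grrann"
  out
}

#' @export
print.summary.grrann <- function(x, ...) {
  print(x$fit)
  cat("  training balanced accuracy:", round(x$train_accuracy, 4), "\n")
  cat("Top regulators by |output weight|:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' @export
coef.grrann <- function(object, layer = c("all", "hidden", "output"), ...) {
  layer <- match.arg(layer)
  switch(layer,
         hidden = object$W1,
         output = stats::setNames(object$W2,
                                  object$architecture$regulator_index),
         all = list(W1 = object$W1, b1 = object$b1,
                    W2 = stats::setNames(
                      object$W2, object$architecture$regulator_index),
                    b2 = object$b2))
}

#' Predict phenotype from expression
#'
#' @param object A fitted `"grrann"` model.
#' @param newdata Standardized expression matrix (samples x genes) aligned to
#'   the model's architecture. Standardize the test set on its own statistics,
#'   never with training-set statistics.
#' @param type `"class"` for 0/1 labels, `"response"` for probabilities.
#' @param threshold Classification cut; a sample is labelled 1 when its
#'   predicted probability is `>= threshold` (so an uninformative model with
#'   probability exactly 0.5 labels everything 1 at the default cut).
#' @param ... Unused.
#' @return Numeric vector of probabilities or 0/1 labels.
#' @export
predict.grrann <- function(object, newdata, type = c("class", "response"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  x <- align_genes(newdata, object$architecture)
  p <- nn_forward(list(W1 = object$W1, b1 = object$b1, W2 = object$W2,
                       b2 = object$b2), x)$yhat
  if (type == "response") p else as.integer(p >= threshold)
}

#' @export
fitted.grrann <- function(object, ...) object$fitted

#' @export
residuals.grrann <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  p <- pmin(pmax(object$fitted, YHAT_EPS), 1 - YHAT_EPS)
  if (type == "response") return(object$y - p)
  sign(object$y - p) *
    sqrt(-2 * (object$y * log(p) + (1 - object$y) * log(1 - p)))
}

#' Diagnostic plots for a fitted model
#'
#' Left: penalized objective per training epoch (non-increasing by
#' construction). Right: output-layer weights by regulator, the quantity the
#' group-lasso penalty sparsifies.
#'
#' @param x A `"grrann"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grrann <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l",
                 xlab = "epoch", ylab = "penalized objective", ...)
  graphics::barplot(x$W2, names.arg = x$architecture$regulator_index,
                    las = 2, cex.names = 0.6, ylab = "output weight W2")
  invisible(x)
}

#' Serialize / restore a fitted model bundle
#'
#' Writes a JSON bundle holding the architecture descriptor, weight arrays,
#' penalty settings, optimizer control and the training trace.
#'
#' @param object A `"grrann"` fit.
#' @param path JSON file path.
#' @return `write_grrann()` returns `path` invisibly; `read_grrann()` the
#'   restored `"grrann"` object (without training data fields).
#' @export
write_grrann <- function(object, path) {
  stopifnot(inherits(object, "grrann"))
  arch <- object$architecture
  idx <- which(arch$mask == 1, arr.ind = TRUE)
  jsonlite::write_json(
    list(gene_index = arch$gene_index,
         regulator_index = arch$regulator_index,
         edges = data.frame(regulator = arch$regulator_index[idx[, 1]],
                            gene = arch$gene_index[idx[, 2]],
                            sign = arch$signs[idx]),
         W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2,
         lambda = object$lambda, alpha = object$alpha,
         variant = object$variant,
         control = unclass(object$control),
         trace = object$trace, epochs = object$epochs,
         converged = object$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grrann
#' @export
read_grrann <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- matrix(0, length(d$regulator_index), length(d$gene_index),
                 dimnames = list(d$regulator_index, d$gene_index))
  signs <- mask
  i <- match(d$edges$regulator, d$regulator_index)
  j <- match(d$edges$gene, d$gene_index)
  mask[cbind(i, j)] <- 1
  signs[cbind(i, j)] <- d$edges$sign
  arch <- new_arch(d$gene_index, d$regulator_index, mask, signs)
  ctl <- do.call(grrann_control, d$control[!vapply(d$control, is.null,
                                                   logical(1))])
  W1 <- matrix(d$W1, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  structure(list(W1 = W1, b1 = d$b1,
                 W2 = d$W2, b2 = d$b2, architecture = arch,
                 lambda = d$lambda, alpha = d$alpha, variant = d$variant,
                 control = ctl, trace = d$trace, epochs = d$epochs,
                 converged = d$converged,
                 objective = d$trace[length(d$trace)],
                 dropped = arch$regulator_index[abs(d$W2) <= ctl$zero_eps]),
            class = "grrann")
}
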