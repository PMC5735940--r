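# Core network mathematics: forward pass, loss, penalties, masked gradients
# and the proximal-gradient training loop. The user-facing interface lives in
# grrann.R; these internals operate on a plain weight list
#   w = list(W1 = R x G matrix, b1 = length-R, W2 = length-R, b2 = scalar)
# where W1 is supported on the architecture mask (off-mask entries exactly 0).

YHAT_EPS <- 1e-12

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass for a sample matrix X (n x G): ReLU hidden layer, sigmoid
# output. Returns list(yhat, H, Z) so gradients can reuse the activations.
nn_forward <- function(w, X) {
  if (ncol(X) != ncol(w$W1))
    stop("dimension mismatch: ", ncol(X), " input genes vs ", ncol(w$W1),
         " architecture genes")
  Z <- tcrossprod(X, w$W1)                      # n x R pre-activations
  Z <- sweep(Z, 2L, w$b1, "+")
  H <- pmax(Z, 0)
  u <- drop(H %*% w$W2) + w$b2
  list(yhat = sigmoid(u), H = H, Z = Z)
}

# Mean negative log-likelihood of Bernoulli labels; predictions clipped away
# from 0/1 to keep the logs finite.
cross_entropy <- function(y, yhat) {
  if (length(y) == 0L) stop("cross_entropy: empty input")
  if (length(y) != length(yhat)) stop("cross_entropy: length mismatch")
  yhat <- pmin(pmax(yhat, YHAT_EPS), 1 - YHAT_EPS)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

# Per-variant penalty decomposition.
#   c1_sq : coefficient of sum(W1^2)        (smooth; 0 when absent)
#   c2_sq : coefficients of rho-weighted W2^2 (smooth vector; 0 when absent)
#   t1    : l1 coefficient on W1 entries     (nonsmooth scalar)
#   t2    : l1 coefficients on W2 entries    (nonsmooth vector, sqrt(rho)-scaled)
# Biases are never penalized. half_l1/half_l2 use the full lambda on their
# surviving term (they correspond to alpha = 0 and alpha = 1 respectively).
penalty_terms <- function(lambda, alpha, rho, variant) {
  if (lambda < 0) stop("negative lambda")
  sr <- sqrt(rho)
  zero <- rep(0, length(rho))
  switch(variant,
    grrann  = list(c1_sq = alpha * lambda, c2_sq = zero, t1 = 0,
                   t2 = (1 - alpha) * lambda * sr),
    half_l2 = list(c1_sq = lambda, c2_sq = zero, t1 = 0, t2 = zero),
    half_l1 = list(c1_sq = 0, c2_sq = zero, t1 = 0, t2 = lambda * sr),
    full_l1 = list(c1_sq = 0, c2_sq = zero, t1 = alpha * lambda,
                   t2 = (1 - alpha) * lambda * sr),
    full_l2 = list(c1_sq = alpha * lambda, c2_sq = (1 - alpha) * lambda * sr,
                   t1 = 0, t2 = zero),
    stop("unknown penalty variant: ", variant))
}

# Total penalty value g(alpha, lambda, W). `squared_l2 = FALSE` switches the
# ridge term on W1 from sum-of-squares to the unsquared Frobenius norm.
nn_penalty <- function(w, lambda, alpha, rho, variant, squared_l2 = TRUE) {
  pt <- penalty_terms(lambda, alpha, rho, variant)
  l2w1 <- if (squared_l2) sum(w$W1^2) else sqrt(sum(w$W1^2))
  pt$c1_sq * l2w1 + sum(pt$c2_sq * w$W2^2) +
    pt$t1 * sum(abs(w$W1)) + sum(pt$t2 * abs(w$W2))
}

# Smooth part of the objective: cross-entropy plus all l2 penalty terms.
smooth_value <- function(w, X, y, pt, squared_l2 = TRUE) {
  l2w1 <- if (squared_l2) sum(w$W1^2) else sqrt(sum(w$W1^2))
  cross_entropy(y, nn_forward(w, X)$yhat) +
    pt$c1_sq * l2w1 + sum(pt$c2_sq * w$W2^2)
}

# Analytic gradient of the smooth part via backpropagation; W1 gradient is
# masked so off-mask entries never move.
smooth_grad <- function(w, X, y, pt, mask, squared_l2 = TRUE) {
  n <- nrow(X)
  fw <- nn_forward(w, X)
  d <- (fw$yhat - y) / n                        # d(mean CE)/d u_i
  gb2 <- sum(d)
  gW2 <- drop(crossprod(fw$H, d)) + 2 * pt$c2_sq * w$W2
  Gz <- (d %o% w$W2) * (fw$Z > 0)               # n x R
  gb1 <- colSums(Gz)
  gW1 <- crossprod(Gz, X) * mask
  if (pt$c1_sq > 0) {
    gW1 <- gW1 + if (squared_l2) 2 * pt$c1_sq * w$W1
                 else pt$c1_sq * w$W1 / max(sqrt(sum(w$W1^2)), 1e-12)
  }
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

soft_threshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

# Proximal map of the nonsmooth (l1) penalty terms at step size t.
prox_step <- function(w, g, t, pt, mask) {
  W1 <- w$W1 - t * g$W1
  W1 <- if (pt$t1 > 0) soft_threshold(W1, t * pt$t1) * mask else W1 * mask
  list(W1 = W1,
       b1 = w$b1 - t * g$b1,
       W2 = soft_threshold(w$W2 - t * g$W2, t * pt$t2),
       b2 = w$b2 - t * g$b2)
}

# He-style initialization on the masked support; reproducible under seed.
init_weights <- function(arch, seed) {
  R <- nrow(arch$mask); G <- ncol(arch$mask)
  with_seed(seed, {
    W1 <- matrix(0, R, G, dimnames = dimnames(arch$mask))
    on_mask <- which(arch$mask == 1)
    sd_row <- sqrt(2 / pmax(arch$rho, 1))
    W1[on_mask] <- stats::rnorm(length(on_mask)) *
      sd_row[((on_mask - 1) %% R) + 1]
    list(W1 = W1, b1 = rep(0, R),
         W2 = stats::rnorm(R, sd = 0.01), b2 = 0)
  })
}

# Full-batch proximal gradient descent with backtracking line search.
# Monotone: each accepted step satisfies the quadratic-majorizer condition, so
# the penalized objective is non-increasing across epochs. l1 terms are
# handled by soft-thresholding, which produces exact zeros; once a W2 entry is
# zero, the whole hidden unit's contribution (and its W1 gradient) vanishes,
# realizing group drop-out.
fit_weights <- function(arch, X, y, lambda, alpha, variant, control) {
  if (length(unique(y)) < 2L) stop("degenerate labels: both classes required")
  if (nrow(X) != length(y)) stop("X rows and labels differ in length")
  sq <- control$squared_l2
  pt <- penalty_terms(lambda, alpha, arch$rho, variant)
  w <- init_weights(arch, control$seed)
  nonsmooth <- function(w) pt$t1 * sum(abs(w$W1)) + sum(pt$t2 * abs(w$W2))
  f <- smooth_value(w, X, y, pt, sq)
  obj <- f + nonsmooth(w)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  trace <- numeric(control$max_epochs + 1L); trace[1L] <- obj
  t <- control$learning_rate
  converged <- FALSE
  epoch <- 0L
  while (epoch < control$max_epochs) {
    epoch <- epoch + 1L
    g <- smooth_grad(w, X, y, pt, arch$mask, sq)
    repeat {
      cand <- prox_step(w, g, t, pt, arch$mask)
      dW1 <- cand$W1 - w$W1; db1 <- cand$b1 - w$b1
      dW2 <- cand$W2 - w$W2; db2 <- cand$b2 - w$b2
      sq_norm <- sum(dW1^2) + sum(db1^2) + sum(dW2^2) + db2^2
      f_cand <- smooth_value(cand, X, y, pt, sq)
      bound <- f + sum(g$W1 * dW1) + sum(g$b1 * db1) + sum(g$W2 * dW2) +
        g$b2 * db2 + sq_norm / (2 * t)
      if (f_cand <= bound + 1e-12) break
      t <- t / 2
      if (t < 1e-14) stop("line search failed: step size underflow ",
                          "(non-finite or ill-conditioned loss)")
    }
    w <- cand
    f <- f_cand
    obj_new <- f + nonsmooth(w)
    if (!is.finite(obj_new)) stop("non-finite objective at epoch ", epoch)
    trace[epoch + 1L] <- obj_new
    if (abs(obj - obj_new) < control$tol) {
      obj <- obj_new; converged <- TRUE; break
    }
    obj <- obj_new
    t <- min(t * 1.2, 10)
  }
  list(w = w, objective = obj, trace = trace[seq_len(epoch + 1L)],
       epochs = epoch, converged = converged)
}
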