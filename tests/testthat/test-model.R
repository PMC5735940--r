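# Internal math is exercised through grrann:::, the training loop through the
# exported interface.

one_unit_arch <- function(n_genes = 1) {
  rows <- sprintf("r1\tg%d\t+", seq_len(n_genes))
  build_architecture(read_network(write_edge_file(rows)))
}

test_that("forward pass matches closed-form evaluations", {
  arch <- build_architecture(tiny_net())
  w0 <- zero_weights(arch)
  x <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, arch$gene_index))
  expect_equal(grrann:::nn_forward(w0, x)$yhat, rep(0.5, 3))

  a1 <- one_unit_arch(1)
  w <- list(W1 = matrix(2, 1, 1), b1 = 0, W2 = 1, b2 = 0)
  expect_equal(grrann:::nn_forward(w, matrix(1))$yhat, plogis(2))
  # ReLU kills the negative pre-activation
  expect_equal(grrann:::nn_forward(w, matrix(-1))$yhat, 0.5)
  expect_error(grrann:::nn_forward(w, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("cross-entropy matches closed forms and rejects bad input", {
  expect_equal(grrann:::cross_entropy(1, 0.5), log(2))
  expect_equal(grrann:::cross_entropy(0, 0.9), -log(0.1))
  expect_lt(grrann:::cross_entropy(c(1, 0), c(1, 0)), 1e-10)
  expect_error(grrann:::cross_entropy(numeric(), numeric()), "empty")
  expect_error(grrann:::cross_entropy(c(1, 0), 0.5), "length")
})

test_that("penalty variants match their closed forms", {
  # single hidden unit with rho = 4
  arch <- one_unit_arch(4)
  w <- zero_weights(arch)
  for (v in c("grrann", "half_l1", "half_l2", "full_l1", "full_l2"))
    expect_equal(grrann:::nn_penalty(w, 1, 0.5, arch$rho, v), 0)

  w$W2 <- 3
  expect_equal(grrann:::nn_penalty(w, 1, 0, arch$rho, "grrann"),
               sqrt(4) * 3)
  w1 <- zero_weights(arch); w1$W1[1, 1] <- 2; w1$W2 <- 5
  expect_equal(grrann:::nn_penalty(w1, 0.5, 1, arch$rho, "grrann"),
               0.5 * 4)
  # half variants use the full lambda on the surviving term
  expect_equal(grrann:::nn_penalty(w1, 0.5, 0.3, arch$rho, "half_l2"),
               0.5 * 4)
  expect_equal(grrann:::nn_penalty(w1, 0.5, 0.3, arch$rho, "half_l1"),
               0.5 * 2 * 5)
  expect_equal(grrann:::nn_penalty(w1, 0.5, 0.5, arch$rho, "full_l1"),
               0.5 * 0.5 * 2 + 0.5 * 0.5 * 2 * 5)
  expect_equal(grrann:::nn_penalty(w1, 0.5, 0.5, arch$rho, "full_l2"),
               0.5 * 0.5 * 4 + 0.5 * 0.5 * 2 * 25)
  # unsquared ridge option
  w2 <- zero_weights(arch); w2$W1[1, c(1, 2)] <- c(3, 4)
  expect_equal(grrann:::nn_penalty(w2, 1, 1, arch$rho, "grrann",
                                   squared_l2 = FALSE), 5)
  expect_error(grrann:::nn_penalty(w, -1, 0.5, arch$rho, "grrann"),
               "negative lambda")
})

test_that("objective is loss plus penalty and monotone in lambda", {
  arch <- build_architecture(tiny_net())
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, arch$gene_index))
  y <- rep(c(0, 1), 5)
  w <- zero_weights(arch)
  w$W1[arch$mask == 1] <- c(0.5, -0.2, 0.3); w$W2 <- c(0.4, -0.1)
  obj <- function(lam) {
    pt <- grrann:::penalty_terms(lam, 0.5, arch$rho, "grrann")
    grrann:::cross_entropy(y, grrann:::nn_forward(w, x)$yhat) +
      grrann:::nn_penalty(w, lam, 0.5, arch$rho, "grrann")
  }
  expect_equal(obj(0),
               grrann:::cross_entropy(y, grrann:::nn_forward(w, x)$yhat))
  expect_equal(obj(0) + grrann:::nn_penalty(w, 2, 0.5, arch$rho, "grrann"),
               obj(2))
  expect_lte(obj(0.1), obj(0.5))
  # zero weights, balanced labels: exactly log 2
  expect_equal(grrann:::cross_entropy(
    y, grrann:::nn_forward(zero_weights(arch), x)$yhat), log(2))
})

test_that("analytic smooth gradient matches central finite differences", {
  sim <- small_sim(21, num_genes = 30, num_regulators = 4,
                   edges_per_regulator = 5, n_samples = 12,
                   num_active_regulators = 2)
  arch <- build_architecture(sim$network)
  x <- standardize(sim$x); y <- sim$y
  pt <- grrann:::penalty_terms(0.05, 0.5, arch$rho, "grrann")
  w <- grrann:::init_weights(arch, seed = 3)
  ga <- grrann:::smooth_grad(w, x, y, pt, arch$mask)
  h <- 1e-6
  fd <- function(get, set) {
    wp <- set(w, h); wm <- set(w, -h)
    (grrann:::smooth_value(wp, x, y, pt) -
       grrann:::smooth_value(wm, x, y, pt)) / (2 * h)
  }
  # check every on-mask W1 entry plus all b1, W2, b2 coordinates
  errs <- c()
  for (idx in which(arch$mask == 1)) {
    g_num <- fd(NULL, function(w, d) { w$W1[idx] <- w$W1[idx] + d; w })
    errs <- c(errs, abs(g_num - ga$W1[idx]))
  }
  for (i in seq_along(w$b1)) {
    errs <- c(errs, abs(fd(NULL, function(w, d) {
      w$b1[i] <- w$b1[i] + d; w }) - ga$b1[i]))
    errs <- c(errs, abs(fd(NULL, function(w, d) {
      w$W2[i] <- w$W2[i] + d; w }) - ga$W2[i]))
  }
  errs <- c(errs, abs(fd(NULL, function(w, d) { w$b2 <- w$b2 + d; w }) -
                        ga$b2))
  scale <- max(abs(unlist(ga)))
  expect_lt(max(errs) / scale, 1e-6)
})

test_that("training conserves the mask and the objective never increases", {
  sim <- small_sim(31)
  arch <- build_architecture(sim$network)
  fit <- grrann(standardize(sim$x), sim$y, arch, lambda = 0.02,
                control = fast_control(seed = 1))
  expect_identical(sum(abs(fit$W1[arch$mask == 0])), 0)
  expect_true(all(diff(fit$trace) <= 1e-10))
  # determinism under the seed
  fit2 <- grrann(standardize(sim$x), sim$y, arch, lambda = 0.02,
                 control = fast_control(seed = 1))
  expect_identical(fit$W1, fit2$W1)
  expect_identical(fit$W2, fit2$W2)
})

test_that("zeroing an output weight equals deleting the hidden unit", {
  sim <- small_sim(41, num_genes = 60, num_regulators = 6, n_samples = 40)
  arch <- build_architecture(sim$network)
  x <- standardize(sim$x)
  fit <- grrann(x, sim$y, arch, lambda = 0.005,
                control = fast_control(seed = 2))
  i <- 3L
  w_zero <- list(W1 = fit$W1, b1 = fit$b1,
                 W2 = replace(fit$W2, i, 0), b2 = fit$b2)
  w_del <- list(W1 = fit$W1[-i, , drop = FALSE], b1 = fit$b1[-i],
                W2 = fit$W2[-i], b2 = fit$b2)
  expect_equal(grrann:::nn_forward(w_zero, x)$yhat,
               grrann:::nn_forward(w_del, x)$yhat)
})

test_that("huge lambda silences every regulator; lambda 0 leaves signal", {
  sim <- small_sim(51, n_samples = 20)
  arch <- build_architecture(sim$network)
  x <- standardize(sim$x)
  sat <- grrann(x, sim$y, arch, lambda = 1000,
                control = fast_control(seed = 1))
  expect_true(all(abs(sat$W2) <= sat$control$zero_eps))
  expect_equal(length(sat$dropped), length(arch$regulator_index))
  free <- grrann(x, sim$y, arch, lambda = 0,
                 control = fast_control(seed = 1))
  expect_gt(max(abs(free$W2)), 1e-3)
})

test_that("output support shrinks along the lambda path (soft monotonicity)", {
  sim <- small_sim(61)
  arch <- build_architecture(sim$network)
  x <- standardize(sim$x)
  grid <- 10^seq(log10(0.003), log10(0.3), length.out = 8)
  nz <- vapply(grid, function(l)
    sum(abs(grrann(x, sim$y, arch, lambda = l,
                   control = fast_control(seed = 4))$W2) > 1e-8),
    numeric(1))
  frac_mono <- mean(diff(nz) <= 0)
  expect_gte(frac_mono, 0.9)
  expect_lt(nz[length(nz)], nz[1])
})

test_that("classification threshold is boundary-inclusive and monotone", {
  arch <- build_architecture(tiny_net())
  sim_x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, arch$gene_index))
  zero_fit <- structure(list(W1 = arch$mask * 0, b1 = c(0, 0), W2 = c(0, 0),
                             b2 = 0, architecture = arch,
                             control = grrann_control()),
                        class = "grrann")
  expect_equal(predict(zero_fit, sim_x), rep(1L, 20))
  expect_equal(predict(zero_fit, sim_x, threshold = 1 - 1e-9), rep(0L, 20))
  sim <- small_sim(71, n_samples = 50)
  arch2 <- build_architecture(sim$network)
  fit <- grrann(standardize(sim$x), sim$y, arch2, lambda = 0.01,
                control = fast_control(seed = 1))
  p_lo <- predict(fit, standardize(sim$x), threshold = 0.3)
  p_hi <- predict(fit, standardize(sim$x), threshold = 0.7)
  expect_true(all(p_hi <= p_lo))
  expect_error(predict(fit, standardize(sim$x), threshold = 1), "threshold")
})

test_that("degenerate labels are rejected", {
  sim <- small_sim(81, n_samples = 20)
  arch <- build_architecture(sim$network)
  expect_error(grrann(standardize(sim$x), rep(1, 20), arch, lambda = 0.1),
               "degenerate labels")
})

test_that("model bundle JSON round trips to identical predictions", {
  sim <- small_sim(91, n_samples = 40)
  arch <- build_architecture(sim$network)
  x <- standardize(sim$x)
  fit <- grrann(x, sim$y, arch, lambda = 0.02,
                control = fast_control(seed = 9))
  f <- tempfile(fileext = ".json")
  write_grrann(fit, f)
  back <- read_grrann(f)
  expect_equal(predict(back, x, type = "response"),
               predict(fit, x, type = "response"))
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$variant, fit$variant)
})
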