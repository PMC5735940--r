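test_that("standardization yields exact population z-scores", {
  x <- cbind(g1 = c(1, 2, 3), g2 = c(4, 0, 2))
  z <- standardize(x)
  expect_equal(z[, "g1"], (c(1, 2, 3) - 2) / sqrt(2 / 3))
  expect_equal(unname(z[1, "g1"]), -1.224745, tolerance = 1e-6)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_equal(unname(colSums(z^2) / 3), c(1, 1))
  # sample-sd option
  z1 <- standardize(x, ddof = 1)
  expect_equal(unname(colSums(z1^2) / 2), c(1, 1))
  expect_warning(zc <- standardize(cbind(a = c(5, 5, 5), b = 1:3)),
                 "constant")
  expect_equal(unname(zc[, "a"]), c(0, 0, 0))
  expect_error(standardize(matrix(1, 1, 3)), "at least 2 samples")
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(balanced_accuracy(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0.5)
  # TP=3, FN=1, TN=2, FP=2
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 0, 0, 1, 1)
  expect_equal(balanced_accuracy(y, p), 0.625)
  # invariant under simultaneous class swap
  expect_equal(balanced_accuracy(1 - y, 1 - p), balanced_accuracy(y, p))
  expect_error(balanced_accuracy(c(1, 1), c(0, 1)), "single class")
})

test_that("stratified folds form a balanced partition", {
  y <- rep(c(0, 1), each = 50)
  fold <- grrann:::stratified_folds(y, 5, seed = 3)
  expect_equal(as.integer(table(fold)), rep(20L, 5))
  expect_true(all(table(fold, y) == 10L))
  expect_equal(sort(unique(fold)), 1:5)
  expect_identical(fold, grrann:::stratified_folds(y, 5, seed = 3))
  expect_error(grrann:::stratified_folds(c(0, 0, 0, 1, 1), 3, 1),
               "too small")
  expect_error(grrann:::stratified_folds(y, 1, 1), "k must be")
})

test_that("cross-validation is seeded and reports the fold mean", {
  sim <- small_sim(5)
  arch <- build_architecture(sim$network)
  cv1 <- cv_grrann(sim$x, sim$y, arch, k = 4, lambda = 0.02,
                   control = fast_control(), seed = 17)
  cv2 <- cv_grrann(sim$x, sim$y, arch, k = 4, lambda = 0.02,
                   control = fast_control(), seed = 17)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_equal(cv1$mean_balanced_accuracy, mean(cv1$fold_accuracies))
  expect_equal(length(cv1$fold_accuracies), 4L)
  # confusion counts cover each test fold exactly
  sizes <- vapply(cv1$confusion, sum, numeric(1))
  expect_equal(sort(as.integer(sizes)), sort(as.integer(table(cv1$folds))))
})

test_that("training weights never depend on the test set", {
  sim <- small_sim(6, n_samples = 60)
  arch <- build_architecture(sim$network)
  te1 <- sim$x + 0
  te2 <- sim$x * 2 + 5
  r1 <- independent_test(sim$x, sim$y, te1, sim$y, arch, lambda = 0.02,
                         control = fast_control(seed = 2))
  r2 <- independent_test(sim$x, sim$y, te2, sim$y, arch, lambda = 0.02,
                         control = fast_control(seed = 2))
  expect_identical(r1$model$W1, r2$model$W1)
  expect_identical(r1$model$W2, r2$model$W2)
  # affine per-sample-preserving rescale of the test set leaves standardized
  # values identical, hence identical accuracy
  expect_equal(r1$balanced_accuracy, r2$balanced_accuracy)
})

test_that("resubstitution beats chance and permuted labels sit near chance", {
  sim <- small_sim(8, effect_size = 4)
  arch <- build_architecture(sim$network)
  resub <- independent_test(sim$x, sim$y, sim$x, sim$y, arch, lambda = 0.02,
                            control = fast_control(seed = 3))
  expect_gt(resub$balanced_accuracy, 0.8)
  # destroy the effect in an unseen cohort: its labels are shuffled
  yperm <- grrann:::with_seed(99, sample(sim$y[51:100]))
  perm <- independent_test(sim$x[1:50, ], sim$y[1:50], sim$x[51:100, ],
                           yperm, arch, lambda = 0.02,
                           control = fast_control(seed = 3))
  expect_lt(abs(perm$balanced_accuracy - 0.5), 0.25)
})

test_that("expression and label files round trip, transpose flag works", {
  sim <- small_sim(9, n_samples = 12, num_genes = 40, num_regulators = 5)
  fx <- tempfile(fileext = ".tsv")
  write_expression(sim$x, fx)
  back <- read_expression(fx)
  expect_equal(back, sim$x, tolerance = 1e-7)
  ft <- tempfile(fileext = ".tsv")
  write_expression(t(sim$x), ft)   # genes in rows
  expect_equal(read_expression(ft, transpose = TRUE), sim$x,
               tolerance = 1e-7)
  fy <- tempfile(fileext = ".tsv")
  write_labels(sim$y, fy)
  expect_equal(read_labels(fy), sim$y)
  # missing values are rejected
  bad <- sim$x; bad[2, 3] <- NA
  write_expression(bad, fx)
  expect_error(read_expression(fx), "missing values")
})
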