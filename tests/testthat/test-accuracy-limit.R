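# The ideal-classifier machinery: assignment probabilities, confusion
# matrices by grid integration and Monte Carlo, the weighted accuracy, and
# the closed-form oracle for the symmetric Gaussian case.

test_that("classification probabilities are correct and numerically safe", {
  sp <- generative_spec(list(gaussian_class(0), gaussian_class(0)))
  expect_equal(classification_probabilities(sp, matrix(1.3)),
               matrix(c(0.5, 0.5), 1), ignore_attr = TRUE)
  sp2 <- two_gaussian_spec(d = 1)
  expect_equal(classification_probabilities(sp2, c(0, 0.7))[1, ],
               c(0.5, 0.5))
  # independent density-ratio oracle at random points
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  q <- classification_probabilities(sp2, X)
  p0 <- dnorm(X[, 1], -0.5) * dnorm(X[, 2])
  p1 <- dnorm(X[, 1], +0.5) * dnorm(X[, 2])
  expect_equal(q[, 1], p0 / (p0 + p1), tolerance = 1e-12)
  expect_true(all(abs(rowSums(q) - 1) < 1e-12))
  # prior weighting
  sp3 <- generative_spec(list(gaussian_class(0), gaussian_class(0)),
                         w = c(0.3, 0.7))
  expect_equal(classification_probabilities(sp3, matrix(0),
                                            use_priors = TRUE)[1, ],
               c(0.3, 0.7))
  # far tail: must not underflow to NaN
  qt <- classification_probabilities(sp2, c(8, 8))
  expect_true(all(is.finite(qt)))
})

test_that("hard assignment takes the argmax with ties to the lowest index", {
  expect_identical(hard_assign(c(0.2, 0.8)), 1L)
  expect_identical(hard_assign(c(0.5, 0.5)), 0L)
  expect_identical(hard_assign(c(0, 0, 1)), 2L)
  expect_identical(hard_assign(rbind(c(0.9, 0.1), c(1, 1) / 2)), c(0L, 0L))
  expect_error(hard_assign(numeric(0)), "empty")
})

test_that("grid confusion matrix is column-stochastic and matches the closed form", {
  # negligible-overlap case: identity matrix
  far <- generative_spec(list(gaussian_class(c(-5, 0)),
                              gaussian_class(c(5, 0))))
  cm <- confusion_matrix_grid(far, grid = grid_spec(-13, 13, 0.02))
  expect_equal(cm$matrix, diag(2), tolerance = 1e-6)
  expect_gt(cm$accuracy, 0.999999)
  # closed-form oracle across separations
  for (d in c(0, 1, 2, 3)) {
    cmd <- confusion_matrix_grid(two_gaussian_spec(d),
                                 grid = grid_spec(spacing = 0.02))
    expect_true(all(abs(colSums(cmd$matrix) - 1) < 1e-3))
    expect_lt(abs(cmd$accuracy - bayes_limit_gaussian_1d(d)), 1e-3)
  }
  # quantitative anchor at the default spacing
  cm1 <- confusion_matrix_grid(two_gaussian_spec(1))
  expect_equal(diag(cm1$matrix), rep(bayes_limit_gaussian_1d(1), 2),
               tolerance = 1e-3)
  # identical densities, unequal priors: the tie rule sends all mass to 0
  same <- generative_spec(list(gaussian_class(c(0, 0)),
                               gaussian_class(c(0, 0))),
                          w = c(0.3, 0.7))
  cms <- confusion_matrix_grid(same, grid = grid_spec(spacing = 0.05))
  expect_equal(cms$matrix, rbind(c(1, 1), c(0, 0)), tolerance = 1e-9)
  expect_equal(cms$accuracy, 0.3, tolerance = 1e-9)
  # dimensions above 3 are refused
  big <- generative_spec(list(gaussian_class(rep(0, 4)),
                              gaussian_class(rep(1, 4))))
  expect_error(confusion_matrix_grid(big), "confusion_matrix_mc")
})

test_that("Monte Carlo confusion matrix agrees with the grid within binomial error", {
  spec <- two_gaussian_spec(1)
  cmg <- confusion_matrix_grid(spec, grid = grid_spec(spacing = 0.02))
  n <- 1e5
  cmm <- confusion_matrix_mc(spec, n_samples = n, seed = 5)
  expect_equal(colSums(cmm$matrix), c(1, 1))
  se <- sqrt(cmg$matrix * (1 - cmg$matrix) / n)
  expect_true(all(abs(cmm$matrix - cmg$matrix) <= 3 * se + 1e-12))
  # determinism under a fixed seed
  expect_identical(cmm$matrix,
                   confusion_matrix_mc(spec, n_samples = n, seed = 5)$matrix)
  expect_warning(confusion_matrix_mc(spec, n_samples = 50, seed = 1),
                 "unstable")
})

test_that("weighted accuracy is the prior-weighted trace", {
  expect_equal(weighted_accuracy(diag(3), c(0.2, 0.3, 0.5)), 1)
  expect_equal(weighted_accuracy(matrix(c(0, 1, 1, 0), 2), c(0.5, 0.5)), 0)
  expect_equal(weighted_accuracy(rbind(c(0.8, 0.1), c(0.2, 0.9)),
                                 c(0.3, 0.7)), 0.87)
  expect_error(weighted_accuracy(rbind(c(1, 0), c(0, 1)), c(1, 1, 1) / 3),
               "match")
})

test_that("closed-form limit behaves at its boundary cases", {
  expect_equal(bayes_limit_gaussian_1d(0), 0.5)
  expect_equal(bayes_limit_gaussian_1d(1), 0.6915, tolerance = 1e-4)
  expect_equal(bayes_limit_gaussian_1d(100), 1)
  expect_error(bayes_limit_gaussian_1d(1, sigma = 0), "positive")
})

test_that("the accuracy limit is monotone in separation and maximal at p_lea = p_gen", {
  amax <- vapply(seq(0, 5, by = 0.5), function(d) {
    confusion_matrix_grid(two_gaussian_spec(d),
                          grid = grid_spec(spacing = 0.05))$accuracy
  }, numeric(1))
  expect_true(all(diff(amax) >= -1e-12))
  # learned densities differing from the truth never help
  set.seed(11)
  for (trial in 1:20) {
    gen <- two_gaussian_spec(runif(1, 0.5, 2))
    pert <- generative_spec(list(
      gaussian_class(gen$densities[[1]]$mean + rnorm(2, sd = 0.3),
                     diag(exp(rnorm(2, sd = 0.3)))),
      gaussian_class(gen$densities[[2]]$mean + rnorm(2, sd = 0.3),
                     diag(exp(rnorm(2, sd = 0.3))))
    ))
    g <- grid_spec(spacing = 0.05)
    a_true <- confusion_matrix_grid(gen, grid = g)$accuracy
    a_pert <- confusion_matrix_grid(gen, ld = pert, grid = g)$accuracy
    expect_lte(a_pert, a_true + 1e-9)
  }
})

test_that("generative specs round-trip through JSON", {
  spec <- two_gaussian_spec(1.3, cov0 = matrix(c(1, 0.4, 0.4, 1), 2))
  path <- tempfile(fileext = ".json")
  write_generative_spec(spec, path)
  back <- read_generative_spec(path)
  expect_equal(back$w, spec$w)
  expect_equal(back$densities[[1]]$mean, spec$densities[[1]]$mean)
  expect_equal(back$densities[[1]]$cov, spec$densities[[1]]$cov,
               ignore_attr = TRUE)
})
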