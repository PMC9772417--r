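# Reference classifiers: posterior contracts, Bayes-optimal behavior on
# Gaussian data, parameter recovery, degenerate inputs, RDE, and the
# network engine's gradients.

test_that("mlp gradients match numerical differentiation", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  for (loss in c("ce", "mse")) {
    output <- if (loss == "ce") "softmax" else "linear"
    Tm <- if (loss == "ce") {
      diag(2)[sample(1:2, 4, replace = TRUE), ]
    } else {
      matrix(rnorm(8), 4, 2)
    }
    par <- classlimit:::mlp_init(c(3, 5, 2), seed = 2)
    acts <- classlimit:::mlp_forward_pass(par, X, output)
    gr <- classlimit:::mlp_gradients(par, acts, Tm, loss)
    for (l in 1:2) {
      for (idx in list(c(1, 1), c(2, 2), c(3, 1))) {
        num <- mlp_numeric_grad(par, X, Tm, output, loss, l, idx[1], idx[2])
        expect_equal(gr$W[[l]][idx[1], idx[2]], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("posterior rows are exactly normalized and predictions are argmax", {
  d <- sample_spec_dataset(two_gaussian_spec(1), 600, seed = 3)
  tr <- training_set(d)
  for (m in list(fit_naive_bayes(d), fit_cmvg(d),
                 fit_perceptron(d, epochs = 5, seed = 1))) {
    q <- predict_proba(m, tr$X)
    expect_true(all(abs(rowSums(q) - 1) < 1e-9))
    expect_identical(predict(m, tr$X), hard_assign(q))
  }
})

test_that("all classifiers reach the Gaussian Bayes limit on 1-D data", {
  for (d_sep in c(1, 2)) {
    spec <- generative_spec(list(gaussian_class(0),
                                 gaussian_class(d_sep)))
    ds <- sample_spec_dataset(spec, 1e5, seed = 40 + d_sep)
    target <- bayes_limit_gaussian_1d(d_sep)
    expect_lt(abs(model_accuracy(fit_naive_bayes(ds), ds) - target), 0.01)
    expect_lt(abs(model_accuracy(fit_cmvg(ds), ds) - target), 0.01)
    expect_lt(abs(model_accuracy(fit_perceptron(ds, epochs = 15, seed = 1),
                                 ds) - target), 0.01)
  }
})

test_that("naive Bayes accuracy is invariant under monotone feature rescaling", {
  d <- sample_spec_dataset(two_gaussian_spec(1), 1e4, seed = 7)
  a_raw <- model_accuracy(fit_naive_bayes(d), d)
  # strictly monotone map per feature preserves marginal ranks
  d2 <- labeled_dataset(sign(d$X) * abs(d$X)^(1 / 3) + 2, d$y,
                        split = d$split, n_classes = 2L)
  a_mono <- model_accuracy(fit_naive_bayes(d2), d2)
  expect_lt(abs(a_mono - a_raw), 0.02)
})

test_that("naive Bayes survives a zero-variance slice via the fallback", {
  set.seed(8)
  X <- cbind(c(rep(1, 50), rnorm(50, 4)), rnorm(100))
  d <- labeled_dataset(X, rep(0:1, each = 50), n_classes = 2L)
  expect_message(m <- fit_naive_bayes(d), "fallback")
  expect_true(all(is.finite(predict_proba(m, X))))
})

test_that("CMVG recovers the generating moments", {
  set.seed(9)
  Sg <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(0.5, 5)
  mu <- rnorm(5)
  X <- rbind(MASS::mvrnorm(5e4, mu, Sg), MASS::mvrnorm(5e4, mu + 2, Sg))
  d <- labeled_dataset(X, rep(0:1, each = 5e4), n_classes = 2L)
  m <- fit_cmvg(d)
  fit0 <- m$classes[[1]]
  tr_rows <- sum(d$y[d$split$train] == 0L)
  expect_true(all(abs(fit0$mu - mu) < 4 * sqrt(diag(Sg) / tr_rows)))
  expect_lt(norm(fit0$sigma - Sg, "F") / norm(Sg, "F"), 0.05)
  # equal-moment classes give an uninformative posterior
  Xe <- MASS::mvrnorm(4000, rep(0, 3), diag(3))
  de <- labeled_dataset(Xe, rep(0:1, 2000), n_classes = 2L)
  qe <- predict_proba(fit_cmvg(de), Xe[1:200, ])
  expect_true(all(abs(qe - 0.5) < 0.1))
})

test_that("random dimensionality expansion is linear and rescues naive Bayes", {
  proj <- rde_projection(2, 20, seed = 2)
  expect_equal(rde_expand(proj, matrix(0, 3, 2)), matrix(0, 3, 20))
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(rde_expand(proj, 3 * X), 3 * rde_expand(proj, X))
  expect_error(rde_projection(5, 5), "exceed")
  # correlation-only class difference: marginals identical, so plain naive
  # Bayes is at chance while the expanded model uses the correlations
  set.seed(10)
  S0 <- matrix(c(1, 0.75, 0.75, 1), 2)
  S1 <- matrix(c(1, -0.75, -0.75, 1), 2)
  X <- rbind(MASS::mvrnorm(5000, c(0, 0), S0),
             MASS::mvrnorm(5000, c(0, 0), S1))
  ord <- sample.int(10000)
  d <- labeled_dataset(X[ord, ], rep(0:1, each = 5000)[ord], n_classes = 2L)
  a_plain <- model_accuracy(fit_naive_bayes(d), d)
  a_rde <- model_accuracy(fit_naive_bayes_rde(d, D2 = 20, seed = 2), d)
  expect_lt(a_plain, 0.56)
  expect_gt(a_rde, a_plain + 0.1)
})

test_that("perceptron separates separable data and gains capacity with width", {
  set.seed(11)
  X <- rbind(matrix(rnorm(400), 200, 2),
             matrix(rnorm(400, mean = 6), 200, 2))
  d <- labeled_dataset(X, rep(0:1, each = 200), n_classes = 2L)
  m <- fit_perceptron(d, epochs = 20, seed = 1)
  expect_gt(model_accuracy(m, d), 0.99)
  expect_true(all(diff(m$net$history$train_loss[c(1, 20)]) < 0))
  # identical seeds reproduce training exactly
  m2 <- fit_perceptron(d, epochs = 20, seed = 1)
  expect_identical(m$net$W, m2$net$W)
  # width sweep on correlated DSC data: wider nets do not do worse
  ctrl <- dsc_control(D = 5, S = 1, C = 0.5, n_vec = 6000L)
  ds <- sample_dsc_dataset(build_class_params(ctrl, seed = 2), 6000L,
                           seed = 3)
  accs <- vapply(c(2L, 10L, 100L), function(h) {
    model_accuracy(fit_perceptron(ds, hidden = h, epochs = 20, seed = 4), ds)
  }, numeric(1))
  expect_gt(accs[2], accs[1] - 0.02)
  expect_gt(accs[3], accs[2] - 0.02)
})

test_that("model accuracy is the fraction of correct test predictions", {
  d <- sample_spec_dataset(two_gaussian_spec(8), 2000, seed = 12)
  expect_equal(model_accuracy(fit_cmvg(d), d), 1.0)
  # label-shuffled balanced data sits at chance
  set.seed(13)
  dsh <- labeled_dataset(d$X, sample(d$y), split = d$split, n_classes = 2L)
  expect_equal(model_accuracy(fit_cmvg(dsh), dsh), 0.5, tolerance = 0.04)
  expect_error(model_accuracy(fit_cmvg(d), list(X = d$X[0, , drop = FALSE],
                                                y = integer(0))),
               "empty")
})
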