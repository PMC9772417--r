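# Reference classifiers under a common fit / predict_proba / predict
# contract: a kernel-density naive Bayes, a correlated multivariate-Gaussian
# (CMVG) Bayes, a one-hidden-layer perceptron, and random dimensionality
# expansion (RDE) as a pre-processing step for naive Bayes.

# Accept either a labeled_dataset (training split used) or a list(X, y).
as_train <- function(train) {
  if (inherits(train, "labeled_dataset")) {
    c(training_set(train), list(n_classes = train$n_classes))
  } else if (is.list(train) && all(c("X", "y") %in% names(train))) {
    list(X = as.matrix(train$X), y = as.integer(train$y),
         n_classes = train$n_classes %||% (max(train$y) + 1L))
  } else {
    stop("`train` must be a labeled_dataset or a list with X and y")
  }
}

as_test <- function(test) {
  if (inherits(test, "labeled_dataset")) {
    test_set(test)
  } else if (is.list(test) && all(c("X", "y") %in% names(test))) {
    list(X = as.matrix(test$X), y = as.integer(test$y))
  } else {
    stop("`test` must be a labeled_dataset or a list with X and y")
  }
}

#' Posterior class probabilities of a fitted classifier
#'
#' @param model a fitted classifier.
#' @param X feature matrix.
#' @param ... passed to methods.
#' @return `n x K` matrix of posteriors; rows sum to 1.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' Test accuracy of a fitted classifier
#'
#' Fraction of test rows whose hard prediction equals the label.
#'
#' @param model a fitted classifier.
#' @param test a `labeled_dataset` (its test split is used) or a
#'   `list(X, y)`.
#' @return accuracy in `[0, 1]`.
#' @export
model_accuracy <- function(model, test) {
  te <- as_test(test)
  if (nrow(te$X) == 0L) stop("empty test set")
  mean(predict(model, te$X) == te$y)
}

## ---- naive Bayes with 1-D kernel density estimates ----------------------

# One KDE per (class, feature), Scott-rule bandwidth h = sd * n^(-1/5),
# evaluated through a binned density grid for speed.
fit_kde_1d <- function(x, global_sd) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 training values per (class, feature)")
  s <- stats::sd(x)
  fallback <- FALSE
  h <- s * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate slice: narrow Gaussian around the constant value
    h <- 1e-6 * (global_sd + 1e-12)
    fallback <- TRUE
  }
  lo <- min(x) - 6 * h; hi <- max(x) + 6 * h
  den <- stats::density(x, bw = h, from = lo, to = hi, n = 4096L)
  list(grid = den$x, dens = den$y, bw = h, fallback = fallback)
}

eval_log_kde <- function(kde, xout) {
  y <- stats::approx(kde$grid, kde$dens, xout, yleft = 0, yright = 0)$y
  log(pmax(y, 1e-300))
}

#' Fit a kernel-density naive Bayes classifier
#'
#' One 1-D Gaussian kernel density estimate (Scott-rule bandwidth
#' `sd * n^(-1/5)`) per class and feature; the class likelihood is the
#' product of the marginal densities and the posterior uses a flat prior
#' over classes. A zero-variance (class, feature) slice falls back to a
#' narrow Gaussian of width `1e-6 * (global feature sd + eps)`.
#'
#' @param train a `labeled_dataset` (training split used) or `list(X, y)`.
#' @return object of class `nbayes_model`.
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200), , 2), matrix(rnorm(200, 1.5), , 2))
#' d <- labeled_dataset(X, rep(0:1, each = 100))
#' m <- fit_naive_bayes(d)
#' model_accuracy(m, d)
fit_naive_bayes <- function(train) {
  tr <- as_train(train)
  K <- tr$n_classes; D <- ncol(tr$X)
  global_sd <- apply(tr$X, 2L, stats::sd)
  kdes <- vector("list", K)
  for (c in seq_len(K)) {
    rows <- tr$y == (c - 1L)
    if (sum(rows) < 2L) stop("need >= 2 training rows per class")
    kdes[[c]] <- lapply(seq_len(D), function(f) {
      fit_kde_1d(tr$X[rows, f], global_sd[f])
    })
  }
  if (any(vapply(unlist(kdes, recursive = FALSE), `[[`, TRUE, "fallback"))) {
    message("naive Bayes: zero-variance slice(s) used the narrow-Gaussian fallback")
  }
  structure(list(kdes = kdes, K = K, D = D), class = "nbayes_model")
}

#' @rdname predict_proba
#' @export
predict_proba.nbayes_model <- function(model, X, ...) {
  X <- as.matrix(X)
  stop_if_not_matrix(X, "X")
  if (ncol(X) != model$D) stop("feature dimension mismatch")
  logl <- matrix(0, nrow(X), model$K)
  for (c in seq_len(model$K)) {
    for (f in seq_len(model$D)) {
      logl[, c] <- logl[, c] + eval_log_kde(model$kdes[[c]][[f]], X[, f])
    }
  }
  normalize_log_rows(logl)
}

#' @export
predict.nbayes_model <- function(object, newdata, ...) {
  hard_assign(predict_proba(object, newdata))
}

## ---- correlated multivariate-Gaussian (CMVG) Bayes ----------------------

#' Fit a CMVG Bayes classifier
#'
#' Estimates a mean vector and full covariance matrix per class; the class
#' likelihood is the corresponding multivariate Gaussian density, combined
#' with a flat prior. A singular covariance receives one ridge pass
#' (`lambda = 1e-8 * trace / D` added to the diagonal) before failing.
#'
#' @inheritParams fit_naive_bayes
#' @return object of class `cmvg_model` with per-class `mu`, `sigma`.
#' @export
fit_cmvg <- function(train) {
  tr <- as_train(train)
  K <- tr$n_classes; D <- ncol(tr$X)
  cls <- vector("list", K)
  for (c in seq_len(K)) {
    rows <- tr$y == (c - 1L)
    if (sum(rows) < D + 1L) {
      stop("need at least D + 1 training rows per class for a full covariance")
    }
    mu <- colMeans(tr$X[rows, , drop = FALSE])
    sg <- stats::cov(tr$X[rows, , drop = FALSE])
    ch <- tryCatch(chol(sg), error = function(e) NULL)
    if (is.null(ch)) {
      sg <- sg + diag(1e-8 * sum(diag(sg)) / D, D)
      ch <- tryCatch(chol(sg), error = function(e) {
        stop("class covariance is singular even after ridge regularization")
      })
    }
    cls[[c]] <- list(mu = mu, sigma = sg, chol = ch,
                     logdet = 2 * sum(log(diag(ch))))
  }
  structure(list(classes = cls, K = K, D = D), class = "cmvg_model")
}

#' @rdname predict_proba
#' @export
predict_proba.cmvg_model <- function(model, X, ...) {
  X <- as.matrix(X)
  stop_if_not_matrix(X, "X")
  if (ncol(X) != model$D) stop("feature dimension mismatch")
  logl <- vapply(model$classes, function(cl) {
    Z <- forwardsolve(t(cl$chol), t(X) - cl$mu)
    -0.5 * (colSums(Z^2) + cl$logdet + model$D * log(2 * pi))
  }, numeric(nrow(X)))
  normalize_log_rows(matrix(logl, nrow = nrow(X)))
}

#' @export
predict.cmvg_model <- function(object, newdata, ...) {
  hard_assign(predict_proba(object, newdata))
}

## ---- one-hidden-layer perceptron ----------------------------------------

#' Fit the reference perceptron classifier
#'
#' One ReLU hidden layer (default 100 units) and a softmax output with one
#' unit per class, trained with Adam on categorical cross-entropy
#' (batch size 128, validation split 0.2, no early stopping).
#'
#' @inheritParams fit_naive_bayes
#' @param hidden hidden-layer size.
#' @param epochs training epochs (default 30).
#' @param batch_size mini-batch size.
#' @param validation_split fraction held out to monitor validation loss.
#' @param seed integer seed for reproducible training.
#' @return object of class `perceptron_model`.
#' @export
fit_perceptron <- function(train, hidden = 100L, epochs = 30L,
                           batch_size = 128L, validation_split = 0.2,
                           seed = NULL) {
  tr <- as_train(train)
  # standardize inputs on training statistics (stored for prediction);
  # keeps optimization well-conditioned for features of arbitrary scale
  center <- colMeans(tr$X)
  scale <- apply(tr$X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- scale(tr$X, center = center, scale = scale)
  net <- mlp_train(Xs, tr$y, hidden = hidden, loss = "ce",
                   n_out = tr$n_classes, epochs = epochs,
                   batch_size = batch_size,
                   validation_split = validation_split, seed = seed)
  structure(list(net = net, K = tr$n_classes, D = ncol(tr$X),
                 center = center, scale = scale),
            class = "perceptron_model")
}

#' @rdname predict_proba
#' @export
predict_proba.perceptron_model <- function(model, X, ...) {
  Xs <- scale(as.matrix(X), center = model$center, scale = model$scale)
  mlp_predict_output(model$net, Xs)
}

#' @export
predict.perceptron_model <- function(object, newdata, ...) {
  hard_assign(predict_proba(object, newdata))
}

## ---- random dimensionality expansion (RDE) ------------------------------

#' Random dimensionality expansion
#'
#' Fixes a random `D2 x D` projection matrix with iid standard-normal
#' entries; [rde_expand()] maps each input row `u` to `M %*% u`. The fitted
#' projection object guarantees that train and test data share the same
#' matrix.
#'
#' @param D input dimension.
#' @param D2 expanded dimension (`D2 > D`).
#' @param seed integer seed fixing the matrix.
#' @return object of class `rde_projection`.
#' @export
rde_projection <- function(D, D2, seed = 1L) {
  D <- as.integer(D); D2 <- as.integer(D2)
  if (D2 <= D) stop("D2 must exceed the input dimension D")
  M <- with_seed(seed, matrix(rnorm(D2 * D), D2, D))
  structure(list(M = M, D = D, D2 = D2, seed = as.integer(seed)),
            class = "rde_projection")
}

#' @rdname rde_projection
#' @param proj an `rde_projection`.
#' @param X `n x D` input matrix.
#' @return `rde_expand` returns the `n x D2` expanded matrix.
#' @export
rde_expand <- function(proj, X) {
  stopifnot(inherits(proj, "rde_projection"))
  X <- as.matrix(X)
  if (ncol(X) != proj$D) stop("feature dimension mismatch")
  X %*% t(proj$M)
}

#' Naive Bayes on randomly expanded features
#'
#' Convenience wrapper: expand the training features with a fixed random
#' projection, then fit the KDE naive Bayes on the expanded features. The
#' projection travels with the model so predictions use the same matrix.
#'
#' @inheritParams fit_naive_bayes
#' @param D2 expanded dimension.
#' @param seed seed for the projection matrix.
#' @return object of class `rde_nbayes_model`.
#' @export
fit_naive_bayes_rde <- function(train, D2 = 20L, seed = 1L) {
  tr <- as_train(train)
  proj <- rde_projection(ncol(tr$X), D2, seed = seed)
  nb <- fit_naive_bayes(list(X = rde_expand(proj, tr$X), y = tr$y,
                             n_classes = tr$n_classes))
  structure(list(proj = proj, nb = nb, K = tr$n_classes, D = ncol(tr$X)),
            class = "rde_nbayes_model")
}

#' @rdname predict_proba
#' @export
predict_proba.rde_nbayes_model <- function(model, X, ...) {
  predict_proba(model$nb, rde_expand(model$proj, as.matrix(X)))
}

#' @export
predict.rde_nbayes_model <- function(object, newdata, ...) {
  hard_assign(predict_proba(object, newdata))
}

#' Fit one of the reference classifiers by name
#'
#' @param name one of `"nbayes"`, `"cmvg"`, `"perceptron"`, `"nbayes_rde"`.
#' @param train training data.
#' @param seed seed passed to stochastic fitters.
#' @param hidden,epochs,batch_size perceptron settings (ignored by the
#'   Bayesian models).
#' @param D2 expanded dimension for `"nbayes_rde"` (ignored otherwise).
#' @return a fitted classifier.
#' @export
fit_classifier <- function(name, train, seed = NULL, hidden = 100L,
                           epochs = 30L, batch_size = 128L, D2 = 20L) {
  switch(name,
    nbayes = fit_naive_bayes(train),
    cmvg = fit_cmvg(train),
    perceptron = fit_perceptron(train, hidden = hidden, epochs = epochs,
                                batch_size = batch_size, seed = seed),
    nbayes_rde = fit_naive_bayes_rde(train, D2 = D2, seed = seed %||% 1L),
    stop("unknown classifier: ", name)
  )
}
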