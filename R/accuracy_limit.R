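# The ideal-classifier accuracy limit. Given known class-conditional
# densities p_gen(x|i) with priors w_i, the confusion matrix of the ideal
# classifier C_ji = integral of qhat(j|x) p_gen(x|i) dx is evaluated either
# by Riemann summation on a regular grid (dim <= 3) or by Monte Carlo
# sampling; the weighted trace is the accuracy limit A_max.

#' Gaussian class-conditional density
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix (a scalar or vector is promoted to a
#'   diagonal matrix).
#' @return object of class `class_density` that can be evaluated
#'   (log density) and sampled.
#' @export
#' @examples
#' g <- gaussian_class(c(0, 0), diag(2))
gaussian_class <- function(mean, cov = diag(length(mean))) {
  mean <- as.numeric(mean)
  if (!is.matrix(cov)) {
    cov <- diag(rep(as.numeric(cov), length.out = length(mean)),
                nrow = length(mean))
  }
  if (nrow(cov) != length(mean)) stop("mean/cov dimension mismatch")
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("covariance matrix is not positive definite")
  })
  structure(
    list(kind = "gaussian", mean = mean, cov = cov, chol = ch,
         logdet = 2 * sum(log(diag(ch))), dim = length(mean)),
    class = "class_density"
  )
}

#' Analytic class-conditional density
#'
#' Registers an arbitrary density by its log-density function (vectorized
#' over matrix rows) and, optionally, a sampler so the Monte Carlo path can
#' be used.
#'
#' @param logdens function taking an `n x dim` matrix, returning `n` log
#'   densities.
#' @param dim feature dimension.
#' @param sampler optional function taking `n`, returning an `n x dim`
#'   matrix of draws.
#' @return object of class `class_density`.
#' @export
analytic_class <- function(logdens, dim, sampler = NULL) {
  stopifnot(is.function(logdens))
  structure(
    list(kind = "analytic", logdens = logdens, sampler = sampler,
         dim = as.integer(dim)),
    class = "class_density"
  )
}

# Log density of one class at the rows of X.
class_logdens <- function(cl, X) {
  X <- as.matrix(X)
  if (ncol(X) != cl$dim) stop("dimension mismatch in density evaluation")
  if (cl$kind == "gaussian") {
    Z <- forwardsolve(t(cl$chol), t(X) - cl$mean)
    -0.5 * (colSums(Z^2) + cl$logdet + cl$dim * log(2 * pi))
  } else {
    cl$logdens(X)
  }
}

class_sample <- function(cl, n) {
  if (cl$kind == "gaussian") {
    matrix(MASS::mvrnorm(n, mu = cl$mean, Sigma = cl$cov), nrow = n)
  } else if (!is.null(cl$sampler)) {
    cl$sampler(n)
  } else {
    stop("this analytic density has no sampler; Monte Carlo unavailable")
  }
}

#' Generative specification: priors plus class-conditional densities
#'
#' The ground truth of a classification problem: class priors `w_i` and one
#' evaluable density `p_gen(x|i)` per class. The same structure describes a
#' set of learned densities `p_lea(x|i)`; for the theoretical accuracy limit
#' the learned densities equal the generative ones.
#'
#' @param densities list of [gaussian_class()] / [analytic_class()] objects.
#' @param w numeric vector of priors (defaults to uniform); must sum to 1.
#' @return object of class `generative_spec` with fields `densities`, `w`,
#'   `K`, `dim`.
#' @export
#' @examples
#' spec <- generative_spec(list(
#'   gaussian_class(c(-0.5, 0)), gaussian_class(c(0.5, 0))
#' ))
generative_spec <- function(densities, w = NULL) {
  stopifnot(length(densities) >= 2L,
            all(vapply(densities, inherits, TRUE, "class_density")))
  K <- length(densities)
  w <- w %||% rep(1 / K, K)
  if (length(w) != K || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("priors `w` must be nonnegative and sum to 1")
  }
  dims <- vapply(densities, `[[`, 1L, "dim")
  if (length(unique(dims)) != 1L) stop("all densities must share a dimension")
  structure(
    list(densities = densities, w = as.numeric(w), K = K,
         dim = as.integer(dims[1])),
    class = "generative_spec"
  )
}

# n x K matrix of class log densities.
spec_logdens <- function(spec, X) {
  X <- as.matrix(X)
  out <- vapply(spec$densities, function(cl) class_logdens(cl, X),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

#' Classification probabilities under learned densities
#'
#' Evaluates the posterior-style assignment probabilities
#' `q(j|x) = p_lea(x|j) / sum_k p_lea(x|k)` (flat variant) or the
#' prior-weighted variant with weights `w_lea`. Computed in log space so the
#' far tails of the densities do not underflow.
#'
#' @param ld a [generative_spec()] holding the learned densities.
#' @param x a single feature vector or an `n x dim` matrix.
#' @param use_priors if `TRUE`, weight each class likelihood by its prior.
#' @return an `n x K` matrix of probabilities; rows sum to 1. Rows where
#'   every density underflows are returned as the uniform distribution (tie)
#'   with a warning.
#' @export
classification_probabilities <- function(ld, x, use_priors = FALSE) {
  stopifnot(inherits(ld, "generative_spec"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  lp <- spec_logdens(ld, X)
  if (use_priors) lp <- sweep(lp, 2L, log(ld$w), `+`)
  normalize_log_rows(matrix(lp, nrow = nrow(X)))
}

#' Hard class assignment
#'
#' Argmax over assignment probabilities, with ties broken towards the lowest
#' class index. Labels are zero-based.
#'
#' @param q a probability vector of length `K` or an `n x K` matrix.
#' @return integer label(s) in `0 ... K-1`.
#' @export
hard_assign <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) < 1L) stop("empty probability matrix")
    max.col(q, ties.method = "first") - 1L
  } else {
    if (length(q) < 1L) stop("empty probability vector")
    which_max_first(q) - 1L
  }
}

#' Regular evaluation grid
#'
#' @param lo,hi per-dimension bounds (recycled to `dim`).
#' @param spacing grid spacing.
#' @param dim dimension (1-3).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(lo = -8, hi = 8, spacing = 0.01, dim = 2L) {
  dim <- as.integer(dim)
  if (dim < 1L || dim > 3L) stop("grid integration supports dim 1-3 only")
  lo <- rep(lo, length.out = dim); hi <- rep(hi, length.out = dim)
  if (any(lo >= hi)) stop("need lo < hi")
  structure(list(lo = lo, hi = hi, spacing = spacing, dim = dim),
            class = "grid_spec")
}

confusion_result <- function(matrix, w, method, extra = list()) {
  acc <- sum(w * diag(matrix))
  structure(c(list(matrix = matrix, accuracy = acc, w = w, method = method),
              extra),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("<confusion_result> method=%s, accuracy=%.4f\n",
              x$method, x$accuracy))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Confusion matrix of the ideal classifier by grid integration
#'
#' Riemann-sum evaluation of `C_ji = integral qhat(j|x) p_gen(x|i) dx` on a
#' regular grid. Entry `(j, i)` is the probability that a point generated
#' under class `i` is assigned to class `j`; columns sum to 1 up to the
#' density mass outside the grid. With `ld` equal to `gen` the attached
#' weighted accuracy is the theoretical limit `A_max`.
#'
#' @param gen [generative_spec()] of the data source.
#' @param ld learned densities (defaults to `gen`, i.e. the ideal
#'   classifier).
#' @param grid a [grid_spec()]; defaults to `[-8, 8]` with spacing 0.01 in
#'   `gen$dim` dimensions.
#' @param use_priors whether assignment uses prior-weighted probabilities.
#' @param mass_tol warn if the density mass captured by the grid falls short
#'   of 1 by more than this.
#' @return a `confusion_result` (fields `matrix`, `accuracy`, `method`).
#' @export
#' @examples
#' spec <- generative_spec(list(
#'   gaussian_class(c(-0.5, 0)), gaussian_class(c(0.5, 0))
#' ))
#' cm <- confusion_matrix_grid(spec, grid = grid_spec(spacing = 0.05))
#' cm$accuracy
confusion_matrix_grid <- function(gen, ld = gen, grid = NULL,
                                  use_priors = FALSE, mass_tol = 1e-3) {
  stopifnot(inherits(gen, "generative_spec"))
  if (gen$dim > 3L) {
    stop("grid integration is restricted to dim <= 3; use confusion_matrix_mc()")
  }
  grid <- grid %||% grid_spec(dim = gen$dim)
  if (grid$dim != gen$dim) stop("grid dimension mismatch")
  # midpoint rule: cell-centered nodes avoid placing decision boundaries
  # exactly on grid points and double-counting the domain edges
  axes <- lapply(seq_len(grid$dim), function(j) {
    seq(grid$lo[j] + grid$spacing / 2, grid$hi[j], by = grid$spacing)
  })
  cell <- grid$spacing^grid$dim
  K <- gen$K
  counts <- matrix(0, K, K)
  # Chunk over the last axis to bound memory on 3-D grids.
  last <- axes[[grid$dim]]
  chunk <- max(1L, floor(2e6 / prod(lengths(axes)[-grid$dim])))
  for (start in seq(1L, length(last), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(last))
    pts <- as.matrix(expand.grid(c(axes[-grid$dim], list(last[idx])),
                                 KEEP.OUT.ATTRS = FALSE))
    lp_lea <- spec_logdens(ld, pts)
    if (use_priors) lp_lea <- sweep(lp_lea, 2L, log(ld$w), `+`)
    assign <- max.col(lp_lea, ties.method = "first")
    p_gen <- exp(spec_logdens(gen, pts))
    for (j in seq_len(K)) {
      sel <- assign == j
      if (any(sel)) {
        counts[j, ] <- counts[j, ] + colSums(p_gen[sel, , drop = FALSE])
      }
    }
  }
  cm <- counts * cell
  mass <- colSums(cm)
  if (any(1 - mass > mass_tol)) {
    warning(sprintf("density mass outside grid up to %.2g; enlarge the grid",
                    max(1 - mass)))
  }
  confusion_result(cm, gen$w, "grid",
                   list(spacing = grid$spacing, lo = grid$lo, hi = grid$hi))
}

#' Confusion matrix of the ideal classifier by Monte Carlo
#'
#' For each class `i`, draws `n_samples` points from `p_gen(.|i)` and
#' assigns them with the learned densities; column `i` holds the assignment
#' fractions (columns sum to exactly 1).
#'
#' @inheritParams confusion_matrix_grid
#' @param n_samples draws per class.
#' @param seed optional integer seed.
#' @return a `confusion_result`.
#' @export
confusion_matrix_mc <- function(gen, ld = gen, n_samples = 1e5,
                                use_priors = FALSE, seed = NULL) {
  stopifnot(inherits(gen, "generative_spec"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 100L) {
    warning("n_samples < 100 gives unstable confusion estimates")
  }
  with_seed(seed, {
    K <- gen$K
    cm <- matrix(0, K, K)
    for (i in seq_len(K)) {
      Xi <- class_sample(gen$densities[[i]], n_samples)
      q <- classification_probabilities(ld, Xi, use_priors = use_priors)
      a <- hard_assign(q)
      cm[, i] <- tabulate(a + 1L, nbins = K) / n_samples
    }
    confusion_result(cm, gen$w, "monte_carlo", list(n_samples = n_samples))
  })
}

#' Prior-weighted accuracy from a confusion matrix
#'
#' `A = sum_i w_i C_ii`, the probability-weighted trace of the
#' column-stochastic confusion matrix.
#'
#' @param matrix `K x K` confusion matrix with columns summing to about 1.
#' @param w priors summing to 1.
#' @return accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(matrix, w) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("`matrix` must be square")
  }
  if (length(w) != nrow(matrix)) stop("length(w) must match matrix dimension")
  if (abs(sum(w) - 1) > 1e-6) stop("priors must sum to 1")
  sum(w * diag(matrix))
}

#' Closed-form accuracy limit for two equal-prior 1-D Gaussians
#'
#' For two unit-prior Gaussian classes with common standard deviation
#' `sigma` and mean separation `d`, the ideal classifier cuts at the
#' midpoint and achieves accuracy `pnorm(d / (2 * sigma))`. Also exact for
#' spherical multivariate Gaussians separated along one axis. Used as the
#' independent oracle for the numerical integration.
#'
#' @param d mean separation (`>= 0`).
#' @param sigma common standard deviation (`> 0`).
#' @return accuracy in `[0.5, 1]`.
#' @export
#' @examples
#' bayes_limit_gaussian_1d(1) # 0.6915
bayes_limit_gaussian_1d <- function(d, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(d < 0)) stop("d must be nonnegative")
  stats::pnorm(d / (2 * sigma))
}

#' Write / read a generative spec as JSON
#'
#' Gaussian specs only: priors plus per-class mean vector and covariance
#' matrix.
#'
#' @param spec a [generative_spec()] with Gaussian classes.
#' @param path JSON file path.
#' @export
write_generative_spec <- function(spec, path) {
  stopifnot(inherits(spec, "generative_spec"))
  if (!all(vapply(spec$densities, function(d) d$kind, "") == "gaussian")) {
    stop("only Gaussian specs can be serialized")
  }
  obj <- list(
    w = spec$w,
    classes = lapply(spec$densities, function(d) {
      list(mean = d$mean, cov = unclass(d$cov))
    })
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_generative_spec
#' @export
read_generative_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dens <- lapply(obj$classes, function(cl) {
    m <- unlist(cl$mean)
    cv <- do.call(rbind, lapply(cl$cov, unlist))
    gaussian_class(m, cv)
  })
  generative_spec(dens, w = unlist(obj$w))
}
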