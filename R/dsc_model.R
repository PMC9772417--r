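# The DSC model: a two-level ("superstatistical") generator of labeled
# two-class Gaussian datasets. The high-level control triple (D, S, C) fixes
# the meta-distributions from which per-class means and covariances are
# drawn; each drawn parameter set then generates one dataset.

#' DSC control parameters
#'
#' @param D positive integer, number of features.
#' @param S nonnegative real, maximum per-dimension offset of the class-1
#'   mean (class-0 means are always zero).
#' @param C real in `[0, 2]`, correlation level controlling the distribution
#'   of off-diagonal covariance entries.
#' @param n_rep number of independent parameter sets (default 100).
#' @param n_vec number of data vectors per dataset, split evenly over the two
#'   classes (must be even; default 10000).
#' @param seed integer root seed; per-repetition child seeds are derived from
#'   it with [child_seed()].
#' @return an object of class `dsc_control`.
#' @export
#' @examples
#' ctrl <- dsc_control(D = 5, S = 1, C = 0.5, n_rep = 3, n_vec = 1000, seed = 1)
dsc_control <- function(D, S, C, n_rep = 100L, n_vec = 10000L, seed = 1L) {
  D <- as.integer(D); n_rep <- as.integer(n_rep); n_vec <- as.integer(n_vec)
  if (D < 1L) stop("D must be a positive integer")
  if (S < 0) stop("S must be nonnegative")
  if (C < 0 || C > 2) stop("C must lie in [0, 2]")
  if (n_rep < 1L) stop("n_rep must be positive")
  if (n_vec < 2L || n_vec %% 2L != 0L) stop("n_vec must be even and >= 2")
  structure(
    list(D = D, S = S, C = C, n_rep = n_rep, n_vec = n_vec,
         seed = as.integer(seed)),
    class = "dsc_control"
  )
}

#' Draw off-diagonal covariance entries
#'
#' Entries are iid uniform on `[0, C]` for `C <= 1` and uniform on
#' `[C - 1, 1]` for `C > 1`. At `C = 0` all entries are zero (identity
#' covariance); at `C = 2` all entries are one (perfect correlation).
#'
#' @param C correlation level in `[0, 2]`.
#' @param n number of entries to draw.
#' @return numeric vector of length `n`.
#' @export
sample_offdiag_entries <- function(C, n) {
  if (C < 0 || C > 2) stop("C must lie in [0, 2]")
  if (n == 0L) return(numeric(0))
  if (C <= 1) runif(n, min = 0, max = C) else runif(n, min = C - 1, max = 1)
}

#' Repair an indefinite unit-diagonal symmetric matrix
#'
#' Independently drawn off-diagonal entries can produce an indefinite
#' matrix. Negative eigenvalues are replaced by their absolute values and
#' the matrix is reconstructed (a single pass); an already-PSD input is
#' returned unchanged. Taking absolute values keeps the repaired
#' covariance full rank, so repaired class distributions stay
#' nondegenerate: clipping eigenvalues to zero would confine each class to
#' a random subspace and make overlapping classes artificially separable.
#' The diagonal of a repaired matrix can exceed one slightly (it equals
#' `sum_k |lambda_k| v_ik^2 >= 1`); it is deliberately not rescaled, which
#' mirrors how standard multivariate-normal samplers behave when handed an
#' indefinite covariance.
#'
#' @param M symmetric numeric matrix with unit diagonal.
#' @param tol eigenvalue tolerance below which repair is triggered.
#' @return symmetric PSD matrix; unchanged if `M` was already PSD.
#' @export
repair_covariance <- function(M, tol = 1e-10) {
  stop_if_not_matrix(M, "M")
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-12) {
    stop("`M` must be symmetric")
  }
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= -tol) return(M)
  lam <- abs(e$values)
  R <- e$vectors %*% (lam * t(e$vectors))
  (R + t(R)) / 2
}

#' Draw one per-class parameter set from the DSC meta-distributions
#'
#' Class-0 means are exactly zero; class-1 means are iid uniform on
#' `[0, S]`. Both covariance matrices are drawn with unit diagonal and
#' off-diagonals from [sample_offdiag_entries()], then passed through
#' [repair_covariance()] if the draw is indefinite.
#'
#' @param ctrl a [dsc_control()] object.
#' @param seed optional integer seed applied before drawing.
#' @return object of class `dsc_class_params` with fields `mu0`, `mu1`,
#'   `sigma0`, `sigma1`, `D`.
#' @export
build_class_params <- function(ctrl, seed = NULL) {
  stopifnot(inherits(ctrl, "dsc_control"))
  with_seed(seed, {
    D <- ctrl$D
    mu1 <- if (ctrl$S == 0) rep(0, D) else runif(D, 0, ctrl$S)
    draw_sigma <- function() {
      S <- diag(1, D)
      if (D >= 2L) {
        up <- upper.tri(S)
        vals <- sample_offdiag_entries(ctrl$C, sum(up))
        S[up] <- vals
        S <- S + t(S) - diag(diag(S))
        diag(S) <- 1
        S <- repair_covariance(S)
      }
      S
    }
    structure(
      list(mu0 = rep(0, D), mu1 = mu1,
           sigma0 = draw_sigma(), sigma1 = draw_sigma(), D = D),
      class = "dsc_class_params"
    )
  })
}

#' Sample one labeled dataset from a DSC parameter set
#'
#' Draws `n_vec / 2` multivariate-Gaussian vectors per class, shuffles the
#' row order, and attaches a random 80/20 train/test split.
#'
#' @param params a `dsc_class_params` object from [build_class_params()].
#' @param n_vec even number of data vectors in total.
#' @param seed optional integer seed applied before sampling.
#' @return a [labeled_dataset()] with two classes.
#' @export
sample_dsc_dataset <- function(params, n_vec = 10000L, seed = NULL) {
  stopifnot(inherits(params, "dsc_class_params"))
  n_vec <- as.integer(n_vec)
  if (n_vec %% 2L != 0L) stop("n_vec must be even")
  with_seed(seed, {
    half <- n_vec %/% 2L
    X0 <- MASS::mvrnorm(half, mu = params$mu0, Sigma = params$sigma0)
    X1 <- MASS::mvrnorm(half, mu = params$mu1, Sigma = params$sigma1)
    X <- rbind(matrix(X0, nrow = half), matrix(X1, nrow = half))
    y <- rep(c(0L, 1L), each = half)
    ord <- sample.int(n_vec)
    labeled_dataset(X[ord, , drop = FALSE], y[ord], n_classes = 2L)
  })
}

#' Generate all datasets for a DSC control triple
#'
#' Convenience wrapper producing `n_rep` independent (parameter set,
#' dataset) pairs, with child seeds derived from `ctrl$seed` so earlier
#' repetitions are unchanged when `n_rep` grows.
#'
#' @param ctrl a [dsc_control()] object.
#' @return list of length `n_rep`; each element has fields `params` and
#'   `data`.
#' @export
dsc_datasets <- function(ctrl) {
  stopifnot(inherits(ctrl, "dsc_control"))
  lapply(seq_len(ctrl$n_rep), function(k) {
    params <- build_class_params(ctrl, seed = child_seed(ctrl$seed, k, 0L))
    data <- sample_dsc_dataset(params, ctrl$n_vec,
                               seed = child_seed(ctrl$seed, k, 1L))
    list(params = params, data = data)
  })
}

#' RMS of the upper-triangular empirical covariance entries
#'
#' The root-mean-square average of all entries strictly above the diagonal
#' of the empirical covariance matrix of `X_class`; the observable used to
#' verify that the correlation level of generated data tracks `C`.
#'
#' @param X_class numeric matrix of observations from one class
#'   (`n >= 2` rows, `D >= 2` columns).
#' @return nonnegative scalar.
#' @export
empirical_rms_offdiag <- function(X_class) {
  stop_if_not_matrix(X_class, "X_class")
  if (ncol(X_class) < 2L) stop("need at least 2 features for off-diagonals")
  if (nrow(X_class) < 2L) stop("need at least 2 observations")
  S <- stats::cov(X_class)
  v <- S[upper.tri(S)]
  sqrt(mean(v^2))
}
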