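# Shared fixtures and independent oracles, built in code at test time.

# The two-spherical-Gaussian setup: unit-variance 2-D classes at (-1/2, 0)
# and (+1/2, 0) with equal priors.
two_gaussian_spec <- function(d = 1, cov0 = diag(2), cov1 = diag(2)) {
  generative_spec(list(
    gaussian_class(c(-d / 2, 0), cov0),
    gaussian_class(c(+d / 2, 0), cov1)
  ))
}

# Sample a labeled dataset from a two-class Gaussian spec (balanced,
# shuffled, 80/20 split).
sample_spec_dataset <- function(spec, n, seed, transform = NULL) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(MASS::mvrnorm(half, spec$densities[[1]]$mean,
                           spec$densities[[1]]$cov),
             MASS::mvrnorm(n - half, spec$densities[[2]]$mean,
                           spec$densities[[2]]$cov))
  if (!is.null(transform)) X <- pointwise_transform(X, transform)
  y <- rep(c(0L, 1L), c(half, n - half))
  ord <- sample.int(n)
  labeled_dataset(X[ord, , drop = FALSE], y[ord], n_classes = 2L)
}

# Brute-force GDV oracle: plain loops over Eqs. as written, no shared code
# with gdv().
brute_gdv <- function(points, labels) {
  mu <- colMeans(points)
  sdv <- sqrt(colMeans(sweep(points, 2, mu)^2))
  keep <- sdv > 0
  S <- sweep(sweep(points[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdv[keep], "/") * 0.5
  lv <- sort(unique(labels))
  L <- length(lv)
  intra <- numeric(L)
  for (l in seq_len(L)) {
    idx <- which(labels == lv[l])
    tot <- 0; cnt <- 0
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) {
        tot <- tot + sqrt(sum((S[idx[i], ] - S[idx[j], ])^2))
        cnt <- cnt + 1
      }
    }
    intra[l] <- tot / cnt
  }
  inter_sum <- 0; npair <- 0
  for (l in seq_len(L - 1)) {
    for (m in (l + 1):L) {
      il <- which(labels == lv[l]); im <- which(labels == lv[m])
      tot <- 0
      for (i in il) for (j in im) {
        tot <- tot + sqrt(sum((S[i, ] - S[j, ])^2))
      }
      inter_sum <- inter_sum + tot / (length(il) * length(im))
      npair <- npair + 1
    }
  }
  (mean(intra) - inter_sum / npair) / sqrt(sum(keep))
}

# 784-dimensional clustered "spectra": K well-separated blobs in [0, 1].
make_blobs_784 <- function(n, K = 10L, noise = 0.25, seed = 4L) {
  set.seed(seed)
  centers <- matrix(runif(K * 784L), K, 784L)
  y <- sample(0:(K - 1L), n, replace = TRUE)
  X <- centers[y + 1L, , drop = FALSE] +
    noise * matrix(rnorm(n * 784L), n, 784L)
  list(X = pmin(pmax(X, 0), 1), y = y)
}

# Numerical gradient of the mlp loss wrt one weight matrix entry.
mlp_numeric_grad <- function(par, X, Tm, output, loss, l, i, j, eps = 1e-6) {
  f <- function(w) {
    p <- par
    p$W[[l]][i, j] <- w
    out <- classlimit:::mlp_forward_pass(p, X, output)
    classlimit:::mlp_loss(out[[length(out)]], Tm, loss)
  }
  w0 <- par$W[[l]][i, j]
  (f(w0 + eps) - f(w0 - eps)) / (2 * eps)
}
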