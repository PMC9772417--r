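# Embedding analysis: spectral preprocessing of epoch recordings into
# 784-dimensional normalized vectors, unsupervised autoencoder and
# supervised deep-classifier embeddings, metric MDS projection, and
# layer-wise GDV reporting.

#' Spectral preprocessing of epoch recordings
#'
#' Per subject, the concatenated signal is z-scored; each epoch is then
#' transformed with the FFT, the square roots of the magnitudes are taken,
#' and the first `n_keep` values (lowest frequencies) are kept. The pooled
#' vectors are globally min-max normalized to `[0, 1]` and a random 80/20
#' split is attached.
#'
#' @param recs an [epoch_recording()] or a list of them.
#' @param n_keep number of spectral components to keep (default 784).
#' @param seed optional seed for the train/test split.
#' @return a [labeled_dataset()] of `n_keep`-dimensional spectral vectors
#'   with attribute `"provenance"` (subject and epoch of each row).
#' @export
spectral_preprocess <- function(recs, n_keep = 784L, seed = NULL) {
  if (inherits(recs, "epoch_recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1L,
            all(vapply(recs, inherits, TRUE, "epoch_recording")))
  n_keep <- as.integer(n_keep)
  rows <- list(); labs <- character(0); prov <- list()
  for (r in recs) {
    E <- r$epochs
    if (ncol(E) < 2L * n_keep) {
      stop("epochs too short for the requested number of spectral components")
    }
    mu <- mean(E); sdev <- stats::sd(as.numeric(E))
    if (sdev == 0) stop("zero-variance recording")
    Ez <- (E - mu) / sdev
    sp <- Mod(t(stats::mvfft(t(Ez))))[, seq_len(n_keep), drop = FALSE]
    rows[[length(rows) + 1L]] <- sqrt(sp)
    labs <- c(labs, r$labels)
    prov[[length(prov) + 1L]] <- data.frame(
      subject = r$subject, epoch = seq_len(nrow(E)))
  }
  X <- do.call(rbind, rows)
  rng <- range(X)
  X <- (X - rng[1]) / (rng[2] - rng[1])
  y <- match(labs, SLEEP_STAGES) - 1L
  d <- with_seed(seed, labeled_dataset(X, y, n_classes = 5L))
  attr(d, "stages") <- SLEEP_STAGES
  attr(d, "provenance") <- do.call(rbind, prov)
  d
}

#' Encoder/decoder layer sizes
#'
#' The symmetric autoencoder architecture: fully connected ReLU layers
#' `input, 128, 64, 16, 64, 128, input` around a 16-unit bottleneck. The
#' deep classifier shares the `input, 128, 64, 16` encoder and replaces the
#' decoder by a softmax layer.
#'
#' @param input_dim input dimension (default 784).
#' @return integer vector of layer sizes.
#' @export
autoencoder_sizes <- function(input_dim = 784L) {
  c(input_dim, 128L, 64L, 16L, 64L, 128L, input_dim)
}

#' Train the unsupervised autoencoder
#'
#' Minimizes the mean squared error between inputs and reconstructions with
#' Adam. Hidden layers are ReLU, the output layer linear.
#'
#' @param X matrix of (spectral) input vectors, values typically in
#'   `[0, 1]`.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return object of class `autoencoder_model` (wrapping an [mlp_train()]
#'   network).
#' @export
train_autoencoder <- function(X, epochs = 30L, batch_size = 128L,
                              lr = 1e-3, seed = NULL) {
  X <- as.matrix(X)
  sizes <- autoencoder_sizes(ncol(X))
  net <- mlp_train(X, X, hidden = sizes[-c(1L, length(sizes))], loss = "mse",
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   validation_split = 0.2, seed = seed)
  structure(list(net = net, input_dim = ncol(X)),
            class = "autoencoder_model")
}

#' Reconstruction of inputs by a trained autoencoder
#'
#' @param model an `autoencoder_model`.
#' @param X input matrix.
#' @return reconstructed matrix of the same shape.
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "autoencoder_model"))
  mlp_predict_output(model$net, as.matrix(X))
}

#' Train the supervised deep classifier
#'
#' Shares the autoencoder's `input, 128, 64, 16` encoder layers and adds a
#' softmax output with one unit per class, trained on categorical
#' cross-entropy.
#'
#' @param X input matrix.
#' @param y integer labels `0 ... K-1`.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return object of class `deep_classifier_model`.
#' @export
train_deep_classifier <- function(X, y, epochs = 30L, batch_size = 128L,
                                  lr = 1e-3, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  net <- mlp_train(X, y, hidden = c(128L, 64L, 16L), loss = "ce",
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   validation_split = 0.2, seed = seed)
  structure(list(net = net, K = max(y) + 1L, input_dim = ncol(X)),
            class = "deep_classifier_model")
}

#' @export
predict.deep_classifier_model <- function(object, newdata, ...) {
  hard_assign(mlp_predict_output(object$net, as.matrix(newdata)))
}

#' Activations of an embedding-model layer
#'
#' Layer 0 is the raw input; layers 1-3 are the encoder activations of
#' sizes 128, 64 and 16 (the bottleneck) for both the autoencoder and the
#' deep classifier.
#'
#' @param model an `autoencoder_model` or `deep_classifier_model`.
#' @param X input matrix.
#' @param layer layer index.
#' @return activation matrix, rows aligned with `X`.
#' @export
layer_activations <- function(model, X, layer) {
  net <- model$net %||% stop("not a fitted embedding model")
  mlp_layer_activations(net, X, layer)
}

#' Metric multidimensional scaling to two dimensions
#'
#' Stress-minimizing metric MDS (SMACOF iterations) initialized from
#' classical scaling, which makes the result deterministic for a fixed
#' input. Duplicate points are handled.
#'
#' @param points `n x D` matrix (`n >= 3`).
#' @param max_iter maximum SMACOF iterations.
#' @param tol relative stress-change convergence tolerance.
#' @return `n x 2` coordinate matrix with attribute `"stress"` (normalized
#'   Kruskal stress-1).
#' @export
mds_2d <- function(points, max_iter = 100L, tol = 1e-10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points")
  Dm <- as.matrix(stats::dist(points))
  X <- stats::cmdscale(Dm, k = 2L)
  if (ncol(X) < 2L) { # degenerate (e.g. collinear) configurations
    X <- cbind(X, 0)[, 1:2, drop = FALSE]
  }
  stress_of <- function(E) sqrt(sum((Dm - E)^2) / sum(Dm^2))
  E <- as.matrix(stats::dist(X))
  st <- stress_of(E)
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(E > 0, Dm / E, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- (B %*% X) / n
    En <- as.matrix(stats::dist(Xn))
    stn <- stress_of(En)
    if (!is.finite(stn)) break
    improved <- st - stn
    X <- Xn; E <- En; st <- stn
    if (improved >= 0 && improved < tol * max(st, 1e-300)) break
  }
  attr(X, "stress") <- st
  X
}

#' Layer-wise GDV and MDS report
#'
#' For each requested layer, computes the GDV of the layer activations for
#' an identical point subset and a 2-D MDS projection for visualization.
#'
#' @param model an `autoencoder_model` or `deep_classifier_model`.
#' @param X input matrix.
#' @param y class labels aligned with `X`.
#' @param layers layer indices (default `0:3`).
#' @param subsample optional cap on the number of points (applied once, the
#'   same subset for every layer).
#' @param mds_points cap on points entering the MDS projection (`0` skips
#'   MDS entirely).
#' @param seed seed for the subsampling.
#' @return object of class `layer_report`: a list with one element per
#'   layer (`gdv`, `mds`, `n`, `dim`).
#' @export
layerwise_gdv_report <- function(model, X, y, layers = 0:3,
                                 subsample = NULL, mds_points = 1000L,
                                 seed = 1L) {
  X <- as.matrix(X)
  if (!is.null(subsample) && nrow(X) > subsample) {
    keep <- with_seed(seed, sort(sample.int(nrow(X), subsample)))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  mds_idx <- if (mds_points > 0L && nrow(X) > mds_points) {
    with_seed(child_seed(seed, 2L), sort(sample.int(nrow(X), mds_points)))
  } else seq_len(nrow(X))
  out <- lapply(layers, function(l) {
    A <- layer_activations(model, X, l)
    g <- gdv(A, y)
    m <- if (mds_points > 0L) mds_2d(A[mds_idx, , drop = FALSE]) else NULL
    list(layer = l, gdv = g$gdv, gdv_detail = g, mds = m, n = nrow(A),
         dim = ncol(A))
  })
  names(out) <- paste0("L", layers)
  structure(list(layers = out, subsample = subsample %||% nrow(X)),
            class = "layer_report")
}

#' @export
print.layer_report <- function(x, ...) {
  for (l in x$layers) {
    cat(sprintf("L%d (dim %4d): GDV = %+0.4f  (n = %d)\n",
                l$layer, l$dim, l$gdv, l$n))
  }
  invisible(x)
}
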