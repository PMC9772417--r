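# A small fully connected feed-forward network trained with Adam.
# This is the engine behind the one-hidden-layer perceptron classifier, the
# autoencoder and the deep classifier. Hidden layers use ReLU; the output
# layer is softmax (categorical cross-entropy) or linear (mean squared
# error).

mlp_init <- function(sizes, seed = NULL) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1L])) # Glorot uniform
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns the list of layer activations (input first).
mlp_forward_pass <- function(par, X, output) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% par$W[[l]], 2L, par$b[[l]], `+`)
    a <- if (l < L) relu(z) else switch(output,
      softmax = softmax_rows(z),
      linear = z,
      stop("unknown output activation")
    )
    acts[[l + 1L]] <- a
  }
  acts
}

mlp_loss <- function(out, target, loss) {
  switch(loss,
    ce = -mean(log(pmax(rowSums(out * target), 1e-300))),
    mse = mean((out - target)^2),
    stop("unknown loss")
  )
}

# One backward pass; returns gradients. For softmax+CE and linear+MSE the
# output delta has the same simple form (prediction minus target).
mlp_gradients <- function(par, acts, target, loss) {
  L <- length(par$W)
  n <- nrow(target)
  out <- acts[[L + 1L]]
  delta <- switch(loss,
    ce = (out - target) / n,
    mse = 2 * (out - target) / (n * ncol(target))
  )
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train a fully connected network
#'
#' Minimal dense feed-forward network with ReLU hidden layers, trained by
#' mini-batch gradient descent with the Adam update rule. Supports a softmax
#' output with categorical cross-entropy (classification) and a linear
#' output with mean squared error (reconstruction).
#'
#' @param X numeric matrix of inputs (rows are observations).
#' @param target integer class labels `0 ... K-1` for `loss = "ce"`, or a
#'   numeric target matrix for `loss = "mse"`.
#' @param hidden integer vector of hidden-layer sizes.
#' @param loss `"ce"` or `"mse"`.
#' @param n_out number of output units; defaults to the number of classes
#'   (ce) or `ncol(target)` (mse).
#' @param epochs number of passes over the training data (default 30).
#' @param batch_size mini-batch size (default 128).
#' @param lr Adam learning rate.
#' @param validation_split fraction of rows held out to monitor validation
#'   loss (no early stopping).
#' @param seed integer seed controlling initialization, the validation split
#'   and batch shuffling.
#' @return object of class `mlp` with fields `W`, `b`, `sizes`, `loss`,
#'   `output`, `history` (per-epoch train/validation loss).
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 4), 50, 2))
#' m <- mlp_train(X, rep(0:1, each = 50), hidden = 8, epochs = 20, seed = 1)
#' mean(mlp_predict(m, X) == rep(0:1, each = 50))
mlp_train <- function(X, target, hidden = 100L, loss = c("ce", "mse"),
                      n_out = NULL, epochs = 30L, batch_size = 128L,
                      lr = 1e-3, validation_split = 0.2, seed = NULL) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  stop_if_not_matrix(X, "X")
  if (loss == "ce") {
    y <- as.integer(target)
    n_out <- as.integer(n_out %||% (max(y) + 1L))
    Tm <- matrix(0, nrow(X), n_out)
    Tm[cbind(seq_len(nrow(X)), y + 1L)] <- 1
    output <- "softmax"
  } else {
    Tm <- as.matrix(target)
    n_out <- ncol(Tm)
    output <- "linear"
  }
  sizes <- c(ncol(X), as.integer(hidden), n_out)
  par <- mlp_init(sizes, seed = seed)
  L <- length(par$W)
  # Adam state
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  with_seed(if (is.null(seed)) NULL else child_seed(seed, 1L), {
    n <- nrow(X)
    n_val <- if (validation_split > 0 && n > 4L) floor(validation_split * n) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; Ttr <- Tm[tr_idx, , drop = FALSE]
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, length(ord), by = batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + batch_size - 1L, length(ord))]
        acts <- mlp_forward_pass(par, Xtr[bi, , drop = FALSE], output)
        gr <- mlp_gradients(par, acts, Ttr[bi, , drop = FALSE], loss)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$W[[l]]^2
          par$W[[l]] <- par$W[[l]] -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$b[[l]]^2
          par$b[[l]] <- par$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      tr_loss <- mlp_loss(
        mlp_forward_pass(par, Xtr, output)[[L + 1L]], Ttr, loss)
      val_loss <- if (n_val > 0L) {
        mlp_loss(mlp_forward_pass(par, X[val_idx, , drop = FALSE],
                                  output)[[L + 1L]],
                 Tm[val_idx, , drop = FALSE], loss)
      } else NA_real_
      if (!is.finite(tr_loss)) {
        stop(sprintf("training diverged (non-finite loss, seed=%s)",
                     deparse(seed)))
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tr_loss, val_loss = val_loss))
    }
  })
  structure(
    list(W = par$W, b = par$b, sizes = sizes, loss = loss, output = output,
         history = history, seed = seed),
    class = "mlp"
  )
}

#' Network outputs for new inputs
#'
#' @param model a fitted [mlp_train()] model.
#' @param X input matrix.
#' @return output matrix (softmax probabilities or reconstructions).
#' @export
mlp_predict_output <- function(model, X) {
  acts <- mlp_forward_pass(model, as.matrix(X), model$output)
  acts[[length(acts)]]
}

#' @rdname mlp_predict_output
#' @return `mlp_predict` returns hard labels `0 ... K-1` (softmax output
#'   only).
#' @export
mlp_predict <- function(model, X) {
  if (model$output != "softmax") stop("hard labels need a softmax output")
  hard_assign(mlp_predict_output(model, X))
}

#' Activations of an intermediate network layer
#'
#' Layer 0 is the input itself; layer `l >= 1` is the activation of the
#' l-th dense layer.
#'
#' @param model a fitted [mlp_train()] model.
#' @param X input matrix.
#' @param layer layer index (`0 ... length(model$W)`).
#' @return activation matrix, rows aligned with `X`.
#' @export
mlp_layer_activations <- function(model, X, layer) {
  layer <- as.integer(layer)
  if (layer < 0L || layer > length(model$W)) stop("invalid layer index")
  acts <- mlp_forward_pass(model, as.matrix(X), model$output)
  acts[[layer + 1L]]
}
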