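# Internal numerical and RNG helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log values.
#' @return `log(sum(exp(x)))` computed without overflow/underflow.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  fin <- is.finite(mx)
  out <- mx
  if (any(fin)) {
    out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  }
  out
}

# Normalize a matrix of log-likelihood rows into probability rows.
# Rows where every entry underflows to -Inf fall back to the uniform
# distribution (an exact tie).
normalize_log_rows <- function(logp) {
  k <- ncol(logp)
  lse <- row_logsumexp(logp)
  dead <- !is.finite(lse)
  p <- exp(logp - lse)
  if (any(dead)) {
    warning("all class densities underflowed for ", sum(dead),
            " row(s); returning uniform posterior (tie)")
    p[dead, ] <- 1 / k
  }
  p
}

#' Derive a child seed from a root seed and stream indices
#'
#' Deterministic splitting of one root seed into independent child seeds, so
#' that e.g. repetition k of an experiment draws the same data regardless of
#' how many repetitions are requested in total. Uses a small multiplicative
#' hash folded into the 31-bit signed integer range accepted by [set.seed()].
#'
#' @param root integer root seed.
#' @param ... integer stream indices (e.g. repetition, class).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, 3, 0)
child_seed <- function(root, ...) {
  idx <- c(...)
  h <- as.numeric(root) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Argmax with ties broken towards the lowest index.
which_max_first <- function(x) {
  which.max(x) # which.max already returns the first maximum
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
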