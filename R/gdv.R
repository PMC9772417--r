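# The General Discrimination Value (GDV): a z-scored, dimension-normalized
# difference between mean intra-class and mean inter-class Euclidean
# distances. Negative values indicate separated classes; values near zero
# indicate unstructured data. Two Gaussian clusters whose centers are two
# cluster standard deviations apart score -1 by construction.

#' General Discrimination Value
#'
#' Each retained dimension is z-scored (population standard deviation) and
#' multiplied by 1/2; the GDV is then `1/sqrt(D)` times the difference
#' between the average mean intra-class distance and the average mean
#' inter-class distance over all class pairs. Zero-variance dimensions are
#' dropped before z-scoring and `D` counts the retained dimensions.
#'
#' @param points `N x D` numeric matrix.
#' @param labels length-`N` class labels (any atomic type; `>= 2` classes,
#'   each with `>= 2` points).
#' @param subsample optional cap on the number of points entering the
#'   O(N^2) distance computation; rows are sampled without replacement.
#' @param seed seed used when `subsample` is set.
#' @return object of class `gdv_result` with fields `gdv`, `mean_intra`
#'   (named per class), `mean_inter` (matrix over class pairs),
#'   `dropped_dims`, `n`, `dim`.
#' @export
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(400), , 2), matrix(rnorm(400, 2), , 2))
#' gdv(pts, rep(0:1, each = 200))$gdv
gdv <- function(points, labels, subsample = NULL, seed = NULL) {
  points <- as.matrix(points)
  stop_if_not_matrix(points, "points")
  if (length(labels) != nrow(points)) stop("labels must match rows of points")
  lv <- sort(unique(labels))
  L <- length(lv)
  if (L < 2L) stop("need at least 2 classes")
  counts <- table(factor(labels, levels = lv))
  if (any(counts < 2L)) stop("every class needs at least 2 points")
  if (!is.null(subsample) && nrow(points) > subsample) {
    keep <- with_seed(seed, sort(sample.int(nrow(points), subsample)))
    points <- points[keep, , drop = FALSE]
    labels <- labels[keep]
    counts <- table(factor(labels, levels = lv))
    if (any(counts < 2L)) stop("subsample left a class with < 2 points")
  }
  sds <- apply(points, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  keep_dims <- which(sds > 0)
  if (length(keep_dims) == 0L) stop("all dimensions have zero variance")
  dropped <- setdiff(seq_len(ncol(points)), keep_dims)
  S <- points[, keep_dims, drop = FALSE]
  S <- 0.5 * scale(S, center = TRUE,
                   scale = sds[keep_dims])
  S <- matrix(as.numeric(S), nrow = nrow(points))
  li <- match(labels, lv)
  total <- gdv_distance_totals(S, li, L)
  nl <- as.numeric(counts)
  mean_intra <- diag(total) / (nl * (nl - 1))
  names(mean_intra) <- as.character(lv)
  mean_inter <- total / outer(nl, nl)
  dimnames(mean_inter) <- list(as.character(lv), as.character(lv))
  diag(mean_inter) <- NA_real_
  Dk <- length(keep_dims)
  pairs <- which(upper.tri(mean_inter), arr.ind = TRUE)
  g <- (mean(mean_intra) -
          2 / (L * (L - 1)) * sum(mean_inter[pairs])) / sqrt(Dk)
  structure(
    list(gdv = g, mean_intra = mean_intra, mean_inter = mean_inter,
         dropped_dims = dropped, n = nrow(points), dim = Dk),
    class = "gdv_result"
  )
}

# L x L matrix of summed ordered-pair distances (diagonal cells include each
# unordered intra pair twice; self-distances are zero).
gdv_distance_totals <- function(S, labels_idx, L, block = 1024L) {
  n <- nrow(S)
  r <- rowSums(S^2)
  ind <- matrix(0, n, L)
  ind[cbind(seq_len(n), labels_idx)] <- 1
  total <- matrix(0, L, L)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    G <- S[rows, , drop = FALSE] %*% t(S)
    D2 <- pmax(outer(r[rows], r, `+`) - 2 * G, 0)
    Dm <- sqrt(D2)
    by_col <- Dm %*% ind                       # block x L
    agg <- rowsum(by_col, group = labels_idx[rows])
    total[as.integer(rownames(agg)), ] <-
      total[as.integer(rownames(agg)), , drop = FALSE] + agg
  }
  total
}

#' @export
print.gdv_result <- function(x, ...) {
  cat(sprintf("<gdv_result> GDV = %.4f (n = %d, D = %d)\n",
              x$gdv, x$n, x$dim))
  invisible(x)
}

#' Label-permutation null distribution of the GDV
#'
#' Recomputes the GDV under random label shuffles to judge whether an
#' observed value indicates more structure than chance.
#'
#' @inheritParams gdv
#' @param n_perm number of permutations (values below 20 trigger a
#'   warning).
#' @return list with the observed GDV, the null values, their mean and sd,
#'   and the empirical quantile of the observed value within the null.
#' @export
gdv_label_permutation_null <- function(points, labels, n_perm = 100L,
                                       seed = NULL, subsample = NULL) {
  if (n_perm < 20L) warning("n_perm < 20 gives a coarse null distribution")
  observed <- gdv(points, labels, subsample = subsample, seed = seed)$gdv
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      gdv(points, sample(labels), subsample = subsample)$gdv
    }, numeric(1))
  })
  list(
    observed = observed,
    null = nulls,
    null_mean = mean(nulls),
    null_sd = stats::sd(nulls),
    quantile = mean(nulls <= observed)
  )
}
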