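# Labeled feature datasets: the common container passed between the data
# generators, the classifiers and the experiment drivers.

#' Construct a labeled dataset
#'
#' Bundles an `n x D` feature matrix with integer class labels and a
#' train/test index split. Labels are stored zero-based (`0 ... K-1`), the
#' convention used throughout the package.
#'
#' @param X numeric matrix, one row per observation.
#' @param y vector of class labels in `0 ... K-1` (coerced to integer).
#' @param split optional list with integer components `train` and `test`
#'   forming a disjoint, exhaustive partition of `1:nrow(X)`. If `NULL`, a
#'   random 80/20 split is drawn (set the RNG seed beforehand for
#'   reproducibility).
#' @param n_classes number of classes `K`; defaults to `max(y) + 1`.
#' @param train_frac training fraction used when `split` is `NULL`.
#' @return an object of class `labeled_dataset` with fields `X`, `y`,
#'   `split`, `n_classes`.
#' @export
#' @examples
#' set.seed(1)
#' d <- labeled_dataset(matrix(rnorm(40), 20, 2), rep(0:1, each = 10))
#' nrow(training_set(d)$X)
labeled_dataset <- function(X, y, split = NULL, n_classes = NULL,
                            train_frac = 0.8) {
  X <- as.matrix(X)
  stop_if_not_matrix(X, "X")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(is.na(y)) || any(y < 0L)) stop("labels must be non-negative integers")
  n_classes <- as.integer(n_classes %||% (max(y) + 1L))
  if (max(y) >= n_classes) stop("labels exceed declared number of classes")
  if (is.null(split)) split <- make_split(nrow(X), train_frac)
  validate_split(split, nrow(X))
  structure(
    list(X = X, y = y, split = split, n_classes = n_classes),
    class = "labeled_dataset"
  )
}

#' Draw a random train/test index partition
#'
#' @param n number of observations.
#' @param train_frac fraction assigned to the training set.
#' @return list with integer components `train` and `test`.
#' @export
make_split <- function(n, train_frac = 0.8) {
  n_train <- round(train_frac * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

validate_split <- function(split, n) {
  if (!is.list(split) || !all(c("train", "test") %in% names(split))) {
    stop("`split` must be a list with components `train` and `test`")
  }
  idx <- sort(c(split$train, split$test))
  if (length(idx) != n || any(idx != seq_len(n)) ||
      length(intersect(split$train, split$test)) > 0) {
    stop("`split` must be a disjoint, exhaustive partition of 1:n")
  }
  invisible(split)
}

#' @rdname labeled_dataset
#' @param d a `labeled_dataset`.
#' @export
training_set <- function(d) {
  list(X = d$X[d$split$train, , drop = FALSE], y = d$y[d$split$train])
}

#' @rdname labeled_dataset
#' @export
test_set <- function(d) {
  list(X = d$X[d$split$test, , drop = FALSE], y = d$y[d$split$test])
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d x %d, %d classes (train %d / test %d)\n",
    nrow(x$X), ncol(x$X), x$n_classes,
    length(x$split$train), length(x$split$test)
  ))
  invisible(x)
}

#' Write / read a labeled dataset as delimited text plus a JSON sidecar
#'
#' The matrix is stored as CSV (feature columns plus a final `label` column);
#' split indices and any extra metadata go into `<stem>.json`.
#'
#' @param d a `labeled_dataset`.
#' @param stem file path without extension; `<stem>.csv` and `<stem>.json`
#'   are written.
#' @param meta optional named list of additional metadata to record.
#' @return `write_labeled_dataset` returns `stem` invisibly;
#'   `read_labeled_dataset` returns a `labeled_dataset` with attribute
#'   `"meta"`.
#' @export
write_labeled_dataset <- function(d, stem, meta = list()) {
  stopifnot(inherits(d, "labeled_dataset"))
  X <- d$X
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  tab <- data.table::data.table(X, label = d$y)
  data.table::fwrite(tab, paste0(stem, ".csv"))
  side <- c(list(
    n = nrow(d$X), dim = ncol(d$X), n_classes = d$n_classes,
    train = d$split$train, test = d$split$test
  ), meta)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(stem) {
  tab <- data.table::fread(paste0(stem, ".csv"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  y <- tab$label
  X <- as.matrix(tab[, setdiff(names(tab), "label"), with = FALSE])
  d <- labeled_dataset(X, y,
    split = list(train = as.integer(side$train), test = as.integer(side$test)),
    n_classes = as.integer(side$n_classes)
  )
  attr(d, "meta") <- side[setdiff(names(side),
                                  c("n", "dim", "n_classes", "train", "test"))]
  d
}
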