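# Experiment drivers reproducing the study families at configurable scale:
# the accuracy-limit distance sweep, DSC parameter sweeps, the nonlinear
# transformation study, and personalized sleep-stage classification on
# synthetic recordings. Results are long-format records (one row per
# parameter point x repetition x model) so mean curves and per-repetition
# scatters are both derivable.

DEFAULT_CLASSIFIERS <- c("nbayes", "cmvg", "perceptron")

sweep_result <- function(records, experiment, config, seed) {
  records <- as.data.frame(records)
  structure(
    list(records = records, experiment = experiment, config = config,
         seed = seed),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d records\n", x$experiment,
              nrow(x$records)))
  print(utils::head(sweep_summary(x), 12))
  invisible(x)
}

#' Per-point mean and spread of a sweep
#'
#' @param res a `sweep_result`.
#' @return data frame with one row per (parameter value, model) holding the
#'   mean and standard deviation of the metric over repetitions.
#' @export
sweep_summary <- function(res) {
  stopifnot(inherits(res, "sweep_result"))
  r <- res$records
  agg <- stats::aggregate(r$metric,
                          by = list(param = r$param, value = r$value,
                                    model = r$model),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- cbind(agg[, c("param", "value", "model")], as.data.frame(agg$x))
  out[order(out$value, out$model), ]
}

#' Accuracy-limit distance sweep
#'
#' Two 2-D Gaussian classes, class 0 at the origin and class 1 at
#' `(d, 0)`: for each separation `d` the theoretical limit `A_max` is
#' computed by grid integration and the reference classifiers are trained
#' on freshly sampled data.
#'
#' @param d_values separations to sweep.
#' @param cov0,cov1 class covariance matrices (default identity: the
#'   spherical case with closed-form limit `pnorm(d/2)`).
#' @param n_vec samples per dataset (80/20 split).
#' @param classifiers character vector of classifier names (see
#'   [fit_classifier()]); `"nbayes_rde"` is allowed.
#' @param spacing,lo,hi grid-integration parameters.
#' @param n_rep datasets per separation.
#' @param epochs,hidden perceptron settings.
#' @param rde_d2 expanded dimension for `"nbayes_rde"`.
#' @param seed root seed.
#' @return a `sweep_result`; the limit appears as model `"limit"`.
#' @export
run_limit_sweep <- function(d_values = seq(0, 5, by = 0.5),
                            cov0 = diag(2), cov1 = diag(2),
                            n_vec = 10000L,
                            classifiers = DEFAULT_CLASSIFIERS,
                            spacing = 0.01, lo = -8, hi = 8,
                            n_rep = 1L, epochs = 30L, hidden = 100L,
                            rde_d2 = 20L, seed = 1L) {
  rows <- list()
  for (di in seq_along(d_values)) {
    d <- d_values[di]
    spec <- generative_spec(list(
      gaussian_class(c(0, 0), cov0),
      gaussian_class(c(d, 0), cov1)
    ))
    amax <- confusion_matrix_grid(
      spec, grid = grid_spec(lo, hi, spacing, dim = 2L))$accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      param = "d", value = d, rep = 0L, model = "limit", metric = amax)
    for (k in seq_len(n_rep)) {
      ds <- with_seed(child_seed(seed, di, k), {
        n0 <- n_vec %/% 2L
        X <- rbind(class_sample(spec$densities[[1]], n0),
                   class_sample(spec$densities[[2]], n_vec - n0))
        y <- rep(c(0L, 1L), c(n0, n_vec - n0))
        ord <- sample.int(n_vec)
        labeled_dataset(X[ord, , drop = FALSE], y[ord], n_classes = 2L)
      })
      for (i in seq_along(classifiers)) {
        m <- fit_classifier(classifiers[i], ds,
                            seed = child_seed(seed, di, k, i),
                            epochs = epochs, hidden = hidden,
                            D2 = rde_d2)
        rows[[length(rows) + 1L]] <- data.frame(
          param = "d", value = d, rep = k, model = classifiers[i],
          metric = model_accuracy(m, ds))
      }
    }
  }
  sweep_result(do.call(rbind, rows), "limit_sweep",
               list(d_values = d_values, n_vec = n_vec, spacing = spacing,
                    classifiers = classifiers, n_rep = n_rep), seed)
}

#' DSC parameter sweep
#'
#' Sweeps one of the DSC control quantities while holding the other two
#' fixed. For every grid point, `n_rep` independent datasets are generated
#' and each requested classifier is trained from scratch on each dataset.
#'
#' @param sweep which quantity to sweep: `"D"`, `"S"` or `"C"`.
#' @param values grid of values for the swept quantity.
#' @param D,S,C fixed values for the quantities not swept.
#' @param n_rep parameter-set repetitions per grid point (default 10; the
#'   full-scale study uses 100).
#' @param n_vec vectors per dataset.
#' @param classifiers classifier names.
#' @param epochs,hidden perceptron settings.
#' @param seed root seed.
#' @return a `sweep_result` with test accuracies.
#' @export
run_dsc_sweep <- function(sweep = c("S", "D", "C"), values,
                          D = 5L, S = 1.0, C = 0.0,
                          n_rep = 10L, n_vec = 10000L,
                          classifiers = DEFAULT_CLASSIFIERS,
                          epochs = 30L, hidden = 100L, seed = 1L) {
  sweep <- match.arg(sweep)
  rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    Dv <- if (sweep == "D") as.integer(v) else D
    Sv <- if (sweep == "S") v else S
    Cv <- if (sweep == "C") v else C
    ctrl <- dsc_control(Dv, Sv, Cv, n_rep = n_rep, n_vec = n_vec,
                        seed = child_seed(seed, vi))
    sets <- dsc_datasets(ctrl)
    for (k in seq_along(sets)) {
      for (i in seq_along(classifiers)) {
        m <- fit_classifier(classifiers[i], sets[[k]]$data,
                            seed = child_seed(seed, vi, k, i),
                            epochs = epochs, hidden = hidden)
        rows[[length(rows) + 1L]] <- data.frame(
          param = sweep, value = v, rep = k, model = classifiers[i],
          metric = model_accuracy(m, sets[[k]]$data))
      }
    }
  }
  sweep_result(do.call(rbind, rows), "dsc_sweep",
               list(sweep = sweep, values = values, D = D, S = S, C = C,
                    n_rep = n_rep, n_vec = n_vec,
                    classifiers = classifiers), seed)
}

#' Nonlinear transformation study
#'
#' The two-spherical-Gaussian setup (unit-variance classes at `(-1/2, 0)`
#' and `(+1/2, 0)`, equal priors): classifier test accuracies under raw,
#' sin-, sgn- and cos-transformed features. The sign of the first feature
#' carries all class information, so sin and sgn leave accuracy at the
#' limit while cos destroys it.
#'
#' @param transforms subset of `c("raw", "sin", "sgn", "cos")`.
#' @param n_vec samples per dataset.
#' @param n_seeds number of independent repetitions.
#' @param classifiers classifier names.
#' @param epochs,hidden perceptron settings.
#' @param seed root seed.
#' @return a `sweep_result`; `value` encodes the transform index and the
#'   `transform` column the name.
#' @export
run_transform_study <- function(transforms = c("raw", "sin", "sgn", "cos"),
                                n_vec = 10000L, n_seeds = 5L,
                                classifiers = DEFAULT_CLASSIFIERS,
                                epochs = 30L, hidden = 100L, seed = 1L) {
  spec <- generative_spec(list(
    gaussian_class(c(-0.5, 0)), gaussian_class(c(0.5, 0))
  ))
  rows <- list()
  for (ti in seq_along(transforms)) {
    tr <- transforms[ti]
    for (k in seq_len(n_seeds)) {
      ds <- with_seed(child_seed(seed, ti, k), {
        n0 <- n_vec %/% 2L
        X <- rbind(class_sample(spec$densities[[1]], n0),
                   class_sample(spec$densities[[2]], n_vec - n0))
        y <- rep(c(0L, 1L), c(n0, n_vec - n0))
        if (tr != "raw") X <- pointwise_transform(X, tr)
        ord <- sample.int(n_vec)
        labeled_dataset(X[ord, , drop = FALSE], y[ord], n_classes = 2L)
      })
      for (i in seq_along(classifiers)) {
        m <- fit_classifier(classifiers[i], ds,
                            seed = child_seed(seed, ti, k, i),
                            epochs = epochs, hidden = hidden)
        rows[[length(rows) + 1L]] <- data.frame(
          param = "transform", value = ti, transform = tr, rep = k,
          model = classifiers[i], metric = model_accuracy(m, ds))
      }
    }
  }
  sweep_result(do.call(rbind, rows), "transform_study",
               list(transforms = transforms, n_vec = n_vec,
                    n_seeds = n_seeds, classifiers = classifiers), seed)
}

# Fit a classifier after dropping classes absent (or too rare) from the
# training split; absent classes receive zero posterior mass.
fit_on_present <- function(name, train, n_classes, seed = NULL, ...) {
  min_rows <- if (name == "cmvg") ncol(train$X) + 1L else 2L
  counts <- tabulate(train$y + 1L, nbins = n_classes)
  present <- which(counts >= min_rows) - 1L
  if (length(present) < 2L) stop("fewer than 2 trainable classes")
  if (length(present) < n_classes) {
    message(sprintf("%s: %d class(es) absent from training split get zero prior mass",
                    name, n_classes - length(present)))
  }
  keep <- train$y %in% present
  remap <- match(train$y[keep], present) - 1L
  model <- fit_classifier(name, list(X = train$X[keep, , drop = FALSE],
                                     y = remap,
                                     n_classes = length(present)),
                          seed = seed, ...)
  list(model = model, classes = present)
}

predict_present <- function(fit, X) {
  fit$classes[predict(fit$model, X) + 1L]
}

#' Personalized sleep-stage classification on synthetic recordings
#'
#' Emulates the per-subject task: for each synthetic subject, features are
#' extracted from that subject's recording alone, the classifiers are
#' trained on the subject's training split and evaluated on the test
#' split. Stages absent from a training split are assigned zero prior mass.
#'
#' @param n_subjects number of synthetic subjects.
#' @param cfg a [synthetic_sleep_config()] shared by all subjects.
#' @param feature_types subset of `c("fourier", "corr")`.
#' @param classifiers classifier names.
#' @param epochs,hidden perceptron settings.
#' @param seed root seed (per-subject recordings and splits derive from
#'   it).
#' @return a `sweep_result`: one record per subject x feature type x
#'   classifier with the per-subject test accuracy.
#' @export
run_personalized_sleep <- function(n_subjects = 5L,
                                   cfg = synthetic_sleep_config(),
                                   feature_types = c("fourier", "corr"),
                                   classifiers = DEFAULT_CLASSIFIERS,
                                   epochs = 30L, hidden = 100L, seed = 1L) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    rec <- synth_sleep_recording(cfg, seed = child_seed(seed, s),
                                 subject = sprintf("synthetic_%02d", s))
    for (fi in seq_along(feature_types)) {
      ft <- feature_types[fi]
      spec <- if (ft == "fourier") fourier_feature_spec() else
        corr_feature_spec()
      d <- extract_features(rec, spec, seed = child_seed(seed, s, fi))
      tr <- training_set(d); te <- test_set(d)
      for (i in seq_along(classifiers)) {
        fit <- fit_on_present(classifiers[i],
                              c(tr, list(n_classes = d$n_classes)),
                              n_classes = d$n_classes,
                              seed = child_seed(seed, s, fi, i),
                              epochs = epochs, hidden = hidden)
        acc <- mean(predict_present(fit, te$X) == te$y)
        rows[[length(rows) + 1L]] <- data.frame(
          param = "subject", value = s, feature = ft, rep = s,
          model = classifiers[i], metric = acc)
      }
    }
  }
  sweep_result(do.call(rbind, rows), "personalized_sleep",
               list(n_subjects = n_subjects, feature_types = feature_types,
                    classifiers = classifiers, n_epochs = cfg$n_epochs),
               seed)
}

#' Write / read sweep results
#'
#' Long-format CSV plus a JSON manifest (experiment name, config echo, root
#' seed, package version, record count). Reading verifies the manifest
#' against the data.
#'
#' @param res a `sweep_result`.
#' @param stem path without extension.
#' @return `write_results` returns `stem` invisibly; `read_results` a
#'   `sweep_result`.
#' @export
write_results <- function(res, stem) {
  stopifnot(inherits(res, "sweep_result"))
  data.table::fwrite(res$records, paste0(stem, ".csv"))
  jsonlite::write_json(
    list(experiment = res$experiment, config = res$config, seed = res$seed,
         n_records = nrow(res$records),
         package_version = as.character(utils::packageVersion("classlimit"))),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_results
#' @export
read_results <- function(stem) {
  rec <- as.data.frame(data.table::fread(paste0(stem, ".csv")))
  man <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  need <- c("param", "value", "rep", "model", "metric")
  if (!all(need %in% names(rec))) {
    stop("schema violation: expected columns ", paste(need, collapse = ", "))
  }
  if (nrow(rec) != man$n_records) {
    stop("manifest/data mismatch: record counts differ")
  }
  sweep_result(rec, man$experiment, man$config, man$seed)
}
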