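# Epoch-level features for single-channel biosignals: unnormalized Fourier
# magnitudes at tunable frequencies and normalized autocorrelation
# coefficients at tunable lags, plus element-wise nonlinear feature
# transformations and a synthetic sleep-recording generator that emulates
# stage-dependent band-limited EEG structure.

SLEEP_STAGES <- c("Wake", "REM", "N1", "N2", "N3")

#' Epoch-structured recording
#'
#' A sequence of fixed-length signal epochs with one stage label per epoch.
#' The default geometry is 30-second epochs at 256 Hz (7680 samples).
#'
#' @param epochs numeric matrix, one epoch per row, or a list of
#'   equal-length numeric vectors.
#' @param labels per-epoch stage labels from
#'   `c("Wake", "REM", "N1", "N2", "N3")`.
#' @param subject subject identifier.
#' @param rate sampling rate in Hz.
#' @return object of class `epoch_recording`.
#' @export
epoch_recording <- function(epochs, labels, subject = "s1", rate = 256) {
  if (is.list(epochs)) {
    len <- unique(lengths(epochs))
    if (length(len) != 1L) stop("all epochs must have equal length")
    epochs <- do.call(rbind, epochs)
  }
  epochs <- as.matrix(epochs)
  stop_if_not_matrix(epochs, "epochs")
  labels <- as.character(labels)
  if (length(labels) != nrow(epochs)) stop("one label per epoch required")
  if (!all(labels %in% SLEEP_STAGES)) {
    stop("labels must come from the 5-stage alphabet: ",
         paste(SLEEP_STAGES, collapse = ", "))
  }
  structure(
    list(epochs = epochs, labels = labels, subject = subject, rate = rate),
    class = "epoch_recording"
  )
}

#' Fourier-magnitude feature of one epoch
#'
#' The unnormalized magnitude of the projection of the signal onto the
#' sine/cosine pair at frequency `nu`, with the time convention
#' `t_n = n / rate`, `n = 1 ... length(signal)`. At on-grid frequencies
#' (an integer number of cycles per epoch) this equals the discrete Fourier
#' magnitude.
#'
#' @param signal numeric epoch vector.
#' @param nu frequency in Hz (`>= 0`).
#' @param rate sampling rate in Hz.
#' @return nonnegative scalar (vectorized over `nu`).
#' @export
#' @examples
#' t <- (1:7680) / 256
#' fourier_feature(cos(2 * pi * 5 * t), 5) # 3840
fourier_feature <- function(signal, nu, rate = 256) {
  if (any(nu < 0)) stop("frequency must be nonnegative")
  t_n <- seq_along(signal) / rate
  vapply(nu, function(f) {
    ph <- 2 * pi * f * t_n
    sqrt(sum(signal * cos(ph))^2 + sum(signal * sin(ph))^2)
  }, numeric(1))
}

#' Autocorrelation feature of one epoch
#'
#' The normalized autocorrelation coefficient at an integer sample lag:
#' the average of products of mean-centered samples over the valid overlap
#' (length `L - lag`), normalized by the full-epoch population variance.
#' Exactly 1 at lag 0.
#'
#' @param signal numeric epoch vector.
#' @param lag integer lag in samples, `0 <= lag < length(signal)`.
#' @return scalar (vectorized over `lag`).
#' @export
autocorr_feature <- function(signal, lag) {
  n <- length(signal)
  if (any(lag < 0) || any(lag >= n)) stop("lag must satisfy 0 <= lag < length")
  xb <- mean(signal)
  v <- mean((signal - xb)^2)
  if (v == 0) stop("constant epoch: autocorrelation undefined")
  xc <- signal - xb
  vapply(as.integer(lag), function(d) {
    if (d == 0L) return(1)
    mean(xc[1:(n - d)] * xc[(1 + d):n]) / v
  }, numeric(1))
}

#' Feature specifications for epoch recordings
#'
#' `fourier_feature_spec()` holds a frequency grid in `[0, 30]` Hz (default
#' 5, 10, ..., 30 Hz); `corr_feature_spec()` holds integer sample lags
#' (default 1, 3, ..., 11).
#'
#' @param frequencies frequencies in Hz.
#' @param lags integer lags in samples.
#' @return a feature spec object.
#' @export
fourier_feature_spec <- function(frequencies = seq(5, 30, by = 5)) {
  if (any(frequencies < 0 | frequencies > 30)) {
    stop("frequencies must lie in [0, 30] Hz")
  }
  structure(list(frequencies = frequencies), class = "fourier_feature_spec")
}

#' @rdname fourier_feature_spec
#' @export
corr_feature_spec <- function(lags = c(1, 3, 5, 7, 9, 11)) {
  lags <- as.integer(lags)
  if (any(lags <= 0L)) stop("lags must be positive integers")
  structure(list(lags = lags), class = "corr_feature_spec")
}

#' Extract epoch features into a labeled dataset
#'
#' Compresses each epoch into a `D`-dimensional feature vector (one column
#' per frequency or lag), carries the stage labels through as integers
#' `0 ... 4` in the order Wake, REM, N1, N2, N3, and attaches a random
#' 80/20 split.
#'
#' @param rec an [epoch_recording()].
#' @param spec a [fourier_feature_spec()] or [corr_feature_spec()].
#' @param seed optional seed for the train/test split.
#' @return a [labeled_dataset()] with attribute `"stages"` giving the label
#'   alphabet.
#' @export
extract_features <- function(rec, spec, seed = NULL) {
  stopifnot(inherits(rec, "epoch_recording"))
  E <- rec$epochs
  n <- nrow(E); len <- ncol(E)
  if (inherits(spec, "fourier_feature_spec")) {
    t_n <- seq_len(len) / rec$rate
    ph <- outer(t_n, 2 * pi * spec$frequencies)    # len x D
    Xc <- E %*% cos(ph)
    Xs <- E %*% sin(ph)
    X <- sqrt(Xc^2 + Xs^2)
    colnames(X) <- paste0("nu", spec$frequencies)
  } else if (inherits(spec, "corr_feature_spec")) {
    if (any(spec$lags >= len)) stop("lag exceeds epoch length")
    xb <- rowMeans(E)
    Ec <- E - xb
    v <- rowMeans(Ec^2)
    if (any(v == 0)) stop("constant epoch: autocorrelation undefined")
    X <- vapply(spec$lags, function(d) {
      rowMeans(Ec[, 1:(len - d), drop = FALSE] *
                 Ec[, (1 + d):len, drop = FALSE]) / v
    }, numeric(n))
    X <- matrix(X, nrow = n)
    colnames(X) <- paste0("lag", spec$lags)
  } else {
    stop("unknown feature spec")
  }
  y <- match(rec$labels, SLEEP_STAGES) - 1L
  d <- with_seed(seed, labeled_dataset(X, y, n_classes = 5L))
  attr(d, "stages") <- SLEEP_STAGES
  d
}

#' Element-wise nonlinear feature transformation
#'
#' Applies `sin`, `cos` or `sgn` to every matrix entry. The signum maps
#' negative values to -1 and positive values to +1; an exact zero maps
#' to +1 (the continuous-data convention).
#'
#' @param X numeric matrix.
#' @param kind `"sin"`, `"cos"` or `"sgn"`.
#' @return transformed matrix of the same shape.
#' @export
pointwise_transform <- function(X, kind = c("sin", "cos", "sgn")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  stop_if_not_matrix(X, "X")
  switch(kind,
    sin = sin(X),
    cos = cos(X),
    sgn = ifelse(X < 0, -1, 1)
  )
}

#' Configuration of the synthetic sleep-recording generator
#'
#' The generator emulates the qualitative structure of overnight
#' single-channel sleep EEG: each 30-second epoch is band-limited Gaussian
#' noise whose band weights depend on the stage (delta-dominant N3,
#' alpha-rich Wake, mixed N1/REM), multiplied by a per-epoch lognormal
#' amplitude gain whose spread is largest in Wake (making Wake feature
#' distributions widest and inducing positive inter-feature correlations
#' there), plus a broadband noise floor. Stage sequences follow a sticky
#' Markov chain with the configured stationary occupancy.
#'
#' @param n_epochs epochs per subject.
#' @param occupancy named stage probabilities (must sum to 1, all > 0
#'   unless a stage is deliberately absent).
#' @param band_power 5 x 4 matrix of band weights (rows Wake, REM, N1, N2,
#'   N3; columns delta, theta, alpha, beta).
#' @param amp_var per-stage lognormal sd of the epoch amplitude gain.
#' @param band_jitter lognormal sd of independent per-epoch,
#'   per-frequency-bin envelope multipliers; makes stages overlap in
#'   feature space instead of being trivially separable, without inducing
#'   correlations between features at different frequencies.
#' @param noise_floor broadband white-noise amplitude.
#' @param persist probability of staying in the current stage from one
#'   epoch to the next (short-range hypnogram persistence).
#' @param gain_mixture optional length-2 vector of gain factors applied as
#'   an equal-probability per-epoch mixture; a well-separated pair (e.g.
#'   `c(0.4, 2.5)`) makes the feature distributions strongly bimodal and
#'   hence non-Gaussian.
#' @param epoch_len samples per epoch.
#' @param rate sampling rate in Hz.
#' @return object of class `sleep_config`.
#' @export
synthetic_sleep_config <- function(
    n_epochs = 400L,
    occupancy = c(Wake = 0.15, REM = 0.20, N1 = 0.10, N2 = 0.40, N3 = 0.15),
    band_power = NULL,
    amp_var = c(Wake = 0.50, REM = 0.08, N1 = 0.10, N2 = 0.08, N3 = 0.08),
    band_jitter = 0.35,
    noise_floor = 0.3,
    persist = 0.8,
    gain_mixture = NULL,
    epoch_len = 7680L,
    rate = 256) {
  if (is.null(band_power)) {
    band_power <- rbind(
      Wake = c(0.5, 0.7, 2.0, 1.2),
      REM  = c(1.0, 1.5, 0.7, 0.8),
      N1   = c(1.2, 1.8, 0.9, 0.5),
      N2   = c(2.0, 1.5, 0.8, 0.6),
      N3   = c(4.0, 1.0, 0.4, 0.3)
    )
    colnames(band_power) <- c("delta", "theta", "alpha", "beta")
  }
  if (!all(SLEEP_STAGES %in% names(occupancy))) {
    stop("occupancy must be named over all five stages")
  }
  occupancy <- occupancy[SLEEP_STAGES]
  if (any(occupancy < 0) || abs(sum(occupancy) - 1) > 1e-8) {
    stop("occupancy must be nonnegative and sum to 1")
  }
  if (sum(occupancy > 0) < 2) stop("degenerate occupancy: need >= 2 stages")
  if (any(band_power < 0)) stop("band powers must be nonnegative")
  structure(
    list(n_epochs = as.integer(n_epochs), occupancy = occupancy,
         band_power = band_power, amp_var = amp_var[SLEEP_STAGES],
         band_jitter = band_jitter,
         noise_floor = noise_floor, persist = persist,
         gain_mixture = gain_mixture, epoch_len = as.integer(epoch_len),
         rate = rate),
    class = "sleep_config"
  )
}

# Frequency band edges in Hz matching the band_power columns.
SLEEP_BANDS <- rbind(delta = c(0.5, 4), theta = c(4, 8),
                     alpha = c(8, 13), beta = c(13, 30))

#' Generate a synthetic sleep recording
#'
#' @param cfg a [synthetic_sleep_config()].
#' @param seed integer seed; the recording is fully reproducible given
#'   `(cfg, seed)`.
#' @param subject subject identifier.
#' @return an [epoch_recording()] with known ground-truth stage labels.
#' @export
synth_sleep_recording <- function(cfg, seed = 1L, subject = "synthetic") {
  stopifnot(inherits(cfg, "sleep_config"))
  with_seed(seed, {
    n <- cfg$n_epochs; len <- cfg$epoch_len
    # sticky Markov stage sequence with stationary occupancy
    stages <- character(n)
    stages[1] <- sample(SLEEP_STAGES, 1L, prob = cfg$occupancy)
    for (e in seq_len(n - 1L)) {
      stages[e + 1L] <- if (runif(1) < cfg$persist) stages[e] else
        sample(SLEEP_STAGES, 1L, prob = cfg$occupancy)
    }
    # stage envelopes on the two-sided FFT frequency grid; the fold index
    # maps each bin to its mirror so per-bin jitter keeps the spectrum
    # conjugate-symmetric (real signals)
    freqs <- (seq_len(len) - 1L) * cfg$rate / len
    freqs <- pmin(freqs, cfg$rate - freqs)
    fold_idx <- pmin(seq_len(len) - 1L, len - (seq_len(len) - 1L)) + 1L
    n_half <- len %/% 2L + 1L
    envs <- vapply(SLEEP_STAGES, function(s) {
      env <- rep(0, len)
      for (b in seq_len(nrow(SLEEP_BANDS))) {
        inb <- freqs >= SLEEP_BANDS[b, 1] & freqs < SLEEP_BANDS[b, 2]
        env[inb] <- env[inb] + cfg$band_power[s, b]
      }
      env
    }, numeric(len))
    epochs <- matrix(0, n, len)
    for (e in seq_len(n)) {
      s <- stages[e]
      # independent lognormal jitter per frequency bin: spectral
      # variability within a stage without cross-feature correlation
      jit <- exp(stats::rnorm(n_half, sd = cfg$band_jitter))[fold_idx]
      env <- envs[, s] * jit
      white <- stats::rnorm(len)
      shaped <- Re(stats::fft(stats::fft(white) * env,
                              inverse = TRUE)) / len
      gain <- exp(stats::rnorm(1, sd = cfg$amp_var[s]))
      if (!is.null(cfg$gain_mixture)) {
        gain <- gain * sample(cfg$gain_mixture, 1L)
      }
      epochs[e, ] <- gain * shaped + cfg$noise_floor * stats::rnorm(len)
    }
    epoch_recording(epochs, stages, subject = subject, rate = cfg$rate)
  })
}

#' Write / read an epoch recording as delimited text plus a JSON sidecar
#'
#' @param rec an [epoch_recording()].
#' @param stem path without extension.
#' @return `write_epoch_recording` returns `stem` invisibly.
#' @export
write_epoch_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "epoch_recording"))
  data.table::fwrite(data.table::as.data.table(rec$epochs),
                     paste0(stem, ".csv"), col.names = FALSE)
  jsonlite::write_json(
    list(rate = rec$rate, labels = rec$labels, subject = rec$subject),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_epoch_recording
#' @export
read_epoch_recording <- function(stem) {
  E <- as.matrix(data.table::fread(paste0(stem, ".csv"), header = FALSE))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  epoch_recording(unname(E), side$labels, subject = side$subject,
                  rate = side$rate)
}
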