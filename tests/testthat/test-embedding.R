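# Spectral preprocessing, autoencoder and deep-classifier embeddings,
# metric MDS, and layer-wise GDV reports.

test_that("spectral preprocessing yields normalized 784-vectors", {
  cfg <- synthetic_sleep_config(n_epochs = 40L)
  rec <- synth_sleep_recording(cfg, seed = 1)
  d <- spectral_preprocess(rec, seed = 2)
  expect_equal(ncol(d$X), 784L)
  expect_gte(min(d$X), 0)
  expect_lte(max(d$X), 1)
  expect_equal(nrow(d$X), 40L)
  # a pure 5 Hz epoch concentrates power at the 5 Hz bin (bin 151 at a
  # 1/30 Hz resolution, +1 for the DC bin)
  t_n <- (1:7680) / 256
  pure <- rbind(cos(2 * pi * 5 * t_n) + 0.01 * rnorm(7680),
                matrix(rnorm(2 * 7680), 2))
  recp <- epoch_recording(pure, c("N2", "Wake", "N3"))
  dp <- spectral_preprocess(recp, seed = 3)
  expect_equal(which.max(dp$X[1, ]), 151L)
  expect_error(spectral_preprocess(
    epoch_recording(matrix(1, 3, 7680), c("N1", "N2", "N3"))),
    "zero-variance")
})

test_that("spectral vectors discard phase information", {
  set.seed(4)
  x <- as.numeric(Re(fft(fft(rnorm(7680)) *
                           exp(-((0:7679) %% 256) / 64), inverse = TRUE)))
  # randomize phases while preserving the magnitude spectrum
  X <- fft(x)
  n <- length(x)
  ph <- runif(n / 2 - 1, 0, 2 * pi)
  rot <- c(1, exp(1i * ph), 1, exp(-1i * rev(ph)))
  y <- Re(fft(X * rot, inverse = TRUE)) / n
  recs <- epoch_recording(rbind(x, x), c("N2", "N3"))
  recy <- epoch_recording(rbind(y, y), c("N2", "N3"))
  dx <- spectral_preprocess(recs, seed = 1)
  dy <- spectral_preprocess(recy, seed = 1)
  expect_equal(dx$X[1, ], dy$X[1, ], tolerance = 1e-8)
})

test_that("the autoencoder compresses through a 16-unit bottleneck and learns", {
  blobs <- make_blobs_784(360, seed = 5)
  tr <- 1:280; te <- 281:360
  ae <- train_autoencoder(blobs$X[tr, ], epochs = 25, seed = 6)
  expect_identical(ae$net$sizes, c(784L, 128L, 64L, 16L, 64L, 128L, 784L))
  expect_equal(ncol(layer_activations(ae, blobs$X[te, ], 3)), 16L)
  ae0 <- train_autoencoder(blobs$X[tr, ], epochs = 0, seed = 6)
  mse <- function(m) mean((reconstruct(m, blobs$X[te, ]) -
                             blobs$X[te, ])^2)
  expect_lt(mse(ae), 0.5 * mse(ae0))
  # reproducible training under a fixed seed
  ae2 <- train_autoencoder(blobs$X[tr, ], epochs = 25, seed = 6)
  expect_equal(utils::tail(ae$net$history$train_loss, 1),
               utils::tail(ae2$net$history$train_loss, 1),
               tolerance = 1e-12)
})

test_that("supervised training separates classes layer by layer", {
  blobs <- make_blobs_784(600, seed = 7)
  tr <- 1:480; te <- 481:600
  dc <- train_deep_classifier(blobs$X[tr, ], blobs$y[tr], epochs = 30,
                              seed = 8)
  expect_gt(mean(predict(dc, blobs$X[te, ]) == blobs$y[te]), 0.95)
  rep_s <- layerwise_gdv_report(dc, blobs$X[te, ], blobs$y[te],
                                mds_points = 0)
  gds <- vapply(rep_s$layers, `[[`, numeric(1), "gdv")
  # systematic decrease: every layer at least as separated as the input,
  # and a clear overall drop input -> bottleneck
  expect_true(all(gds[-1] < gds[1]))
  expect_lt(gds["L3"], gds["L0"] - 0.1)
  # encoder shapes shared with the autoencoder
  dims <- vapply(rep_s$layers, `[[`, numeric(1), "dim")
  expect_equal(unname(dims), c(784, 128, 64, 16))
  # report recombination: stored GDVs equal direct calls on activations
  a2 <- layer_activations(dc, blobs$X[te, ], 2)
  expect_identical(rep_s$layers$L2$gdv, gdv(a2, blobs$y[te])$gdv)
})

test_that("untrained and shuffled-label networks separate far less than trained ones", {
  blobs <- make_blobs_784(600, seed = 9)
  tr <- 1:480; te <- 481:600
  g_of <- function(model) {
    r <- layerwise_gdv_report(model, blobs$X[te, ], blobs$y[te],
                              layers = c(0, 3), mds_points = 0)
    vapply(r$layers, `[[`, numeric(1), "gdv")
  }
  dc <- train_deep_classifier(blobs$X[tr, ], blobs$y[tr], epochs = 25,
                              seed = 10)
  g_tr <- g_of(dc)
  dc0 <- train_deep_classifier(blobs$X[tr, ], blobs$y[tr], epochs = 0,
                               seed = 10)
  g_un <- g_of(dc0)
  # an untrained projection does not increase separability, and its drift
  # is small next to the trained decrease
  expect_gte(g_un["L3"], g_un["L0"] - 0.02)
  expect_lt(abs(g_un["L3"] - g_un["L0"]),
            0.5 * (g_tr["L0"] - g_tr["L3"]))
  set.seed(11)
  dcs <- train_deep_classifier(blobs$X[tr, ], sample(blobs$y[tr]),
                               epochs = 25, seed = 10)
  g_sh <- g_of(dcs)
  expect_lt(g_tr["L3"], g_sh["L3"])
})

test_that("unsupervised compression does not reduce blob separability", {
  blobs <- make_blobs_784(480, seed = 12)
  tr <- 1:360; te <- 361:480
  ae <- train_autoencoder(blobs$X[tr, ], epochs = 25, seed = 13)
  r <- layerwise_gdv_report(ae, blobs$X[te, ], blobs$y[te], mds_points = 0)
  gds <- vapply(r$layers, `[[`, numeric(1), "gdv")
  expect_true(all(gds[c("L1", "L2", "L3")] <= gds["L0"] + 0.01))
})

test_that("metric MDS recovers planar configurations and improves on classical scaling", {
  set.seed(14)
  P <- matrix(rnorm(60), 30, 2)
  M <- mds_2d(P)
  expect_lt(attr(M, "stress"), 1e-6)
  expect_equal(as.matrix(dist(M)), as.matrix(dist(P)), tolerance = 1e-5)
  # regular tetrahedron: no exact planar embedding exists; the SMACOF
  # refinement must not be worse than the classical-scaling truncation
  Tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  Dm <- as.matrix(dist(Tet))
  Xc <- stats::cmdscale(Dm, k = 2)
  stress <- function(X) sqrt(sum((Dm - as.matrix(dist(X)))^2) / sum(Dm^2))
  M2 <- mds_2d(Tet)
  expect_lte(attr(M2, "stress"), stress(Xc) + 1e-12)
  # duplicate points are tolerated and results are deterministic
  dup <- rbind(P, P[1, ])
  expect_silent(mds_2d(dup))
  expect_identical(mds_2d(P), mds_2d(P))
  expect_error(mds_2d(P[1:2, ]), "3 points")
})
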