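# small architecture used to keep the training tests fast
tinySpec <- function() {
  s <- paqnetSpec(kernels = c(3L, 3L), filters = c(8L, 16L),
                  inputSize = 32L)
  s$dense <- c(32L)
  s
}

tinyBatch <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(32 * 32 * n), ncol = n)
}

test_that("model construction matches the published architectures", {
  m <- buildModel(paqnetSpec(), 1L, seed = 1)
  expect_equal(paramCount(m), 2502273)
  m5 <- buildModel(paqnetSpec(), 5L, seed = 1)
  expect_equal(paramCount(m5), 2502273 + 4 * 129)
  mi <- buildModel(iqdcnnSpec(), 1L, seed = 1)
  expect_equal(mi@spec$dropout, 0.3)
  expect_equal(sum(vapply(mi@layers, function(l) l$type == "conv",
                          logical(1))), 4L)
  # forward pass maps a batch to n outputs per image
  X <- matrix(runif(128 * 128 * 3), ncol = 3)
  p <- predictQuality(m5, X)
  expect_equal(dim(p), c(5L, 3L))
  expect_true(all(is.finite(p)))
  # zero weights produce zero output
  z <- m
  z@weights <- lapply(z@weights, function(w) list(W = w$W * 0, b = w$b * 0))
  expect_true(all(predictQuality(z, X[, 1, drop = FALSE]) == 0))
})

test_that("engine gradients agree with finite differences", {
  tm <- buildModel(tinySpec(), 2L, seed = 3)
  set.seed(5)
  X <- tinyBatch(3, 5)
  # keep every residual far from the MAE kink so central differences are
  # smooth: labels sit 2 units below the initial predictions
  p0 <- predictQuality(tm, X, denormalize = FALSE)
  Y <- p0 - 2 + matrix(runif(6), 2, 3)
  out <- paiq:::.nn_run(tm@layers, tm@weights, X, Y, FALSE, TRUE, 0L,
                        -1L, -1L)
  eps <- 1e-3
  worst <- 0
  for (li in seq_along(tm@weights)) for (what in c("W", "b")) {
    w0 <- tm@weights[[li]][[what]]
    for (k in sample(length(w0), min(3L, length(w0)))) {
      wp <- tm@weights; wp[[li]][[what]][k] <- w0[k] + eps
      wm <- tm@weights; wm[[li]][[what]][k] <- w0[k] - eps
      lp <- paiq:::.nn_run(tm@layers, wp, X, Y, FALSE, FALSE, 0L, -1L,
                           -1L)$loss
      lm <- paiq:::.nn_run(tm@layers, wm, X, Y, FALSE, FALSE, 0L, -1L,
                           -1L)$loss
      fd <- (lp - lm) / (2 * eps)
      # mixed tolerance: fp32 loss evaluation bounds the difference
      # quotient's absolute resolution at ~1e-4
      worst <- max(worst, abs(fd - out$grads[[li]][[what]][k]) -
                            0.02 * abs(fd))
    }
  }
  expect_lt(worst, 5e-4)
})

test_that("labels come from the chosen metrics and are deterministic", {
  d <- tmpDir()
  man <- buildLadder(d, "lab", "vessel", "frame_averaging",
                     levels = c(128L, 2560L), nImages = 3L, seed = 5)
  lab <- labelDataset(man, c("SSIM", "GMSD"))
  expect_equal(nrow(lab), 6L)
  expect_true(all(lab$SSIM >= -1 & lab$SSIM <= 1))
  expect_true(all(lab$GMSD >= 0))
  lab2 <- labelDataset(man, c("SSIM", "GMSD"))
  expect_identical(lab, lab2)
  # a reference paired with itself labels as perfect quality
  csv <- file.path(d, "self.csv")
  rec <- man@records[1, ]
  write.csv(data.frame(dataset = "self", subset = "s", quality_rank = 1,
                       path_test = basename(rec$path_reference),
                       path_reference = basename(rec$path_reference)),
            csv, row.names = FALSE)
  self <- labelDataset(readManifest(csv), "SSIM")
  expect_equal(self$SSIM, 1.0)
})

test_that("training descends, respects patience, and handles degenerate labels", {
  tm <- buildModel(tinySpec(), 1L, seed = 2)
  X <- tinyBatch(160, 7)
  y <- colMeans(X[1:512, ]) * 4 # learnable intensity statistic
  fit <- trainModel(tm, X[, 1:128], y[1:128], X[, 129:160], y[129:160],
                    trainConfig(learningRate = 1e-3, maxEpochs = 6,
                                seed = 1))
  h <- fit@meta$history
  expect_lt(h$train_mae[nrow(h)], h$train_mae[1])
  expect_equal(fit@meta$bestEpoch, which.min(h$val_mae))
  # constant labels converge toward the constant
  cst <- trainModel(buildModel(tinySpec(), 1L, seed = 3),
                    X[, 1:128], rep(0.7, 128), X[, 129:160], rep(0.7, 32),
                    trainConfig(learningRate = 1e-3, maxEpochs = 8,
                                seed = 1))
  p <- predictQuality(cst, X[, 129:160])
  expect_lt(mean(abs(p - 0.7)), 0.01)
  # patience 0 stops after the first non-improving validation epoch
  p0 <- trainModel(buildModel(tinySpec(), 1L, seed = 4),
                   X[, 1:128], y[1:128], X[, 129:160], y[129:160],
                   trainConfig(maxEpochs = 30, patience = 0L, seed = 1))
  h0 <- p0@meta$history
  if (nrow(h0) < 30L) {
    expect_gte(h0$val_mae[nrow(h0)], min(h0$val_mae[-nrow(h0)]))
  }
  # label/model mismatch errors
  expect_error(trainModel(buildModel(tinySpec(), 2L, seed = 1),
                          X[, 1:8], y[1:8], X[, 9:16], y[9:16],
                          trainConfig()), "outputs")
})

test_that("multi-output training normalizes labels and reports per-head metrics", {
  tm <- buildModel(tinySpec(), 2L, seed = 5)
  X <- tinyBatch(120, 11)
  y1 <- colMeans(X[1:512, ]) * 4           # higher-better style label
  y2 <- 0.3 - 0.2 * colMeans(X[513:1024, ]) # plays the lower-better role
  Y <- cbind(SSIM = y1, GMSD = y2)
  fit <- trainModel(tm, X[, 1:96], Y[1:96, ], X[, 97:120], Y[97:120, ],
                    trainConfig(learningRate = 1e-3, maxEpochs = 4,
                                seed = 1))
  expect_equal(fit@meta$metrics, c("SSIM", "GMSD"))
  expect_equal(fit@meta$scaling$sign, c(1, -1))
  ev <- evaluateModel(fit, list(t = list(x = X[, 97:120],
                                         y = Y[97:120, ])))
  expect_equal(nrow(ev), 2L)
  expect_true(all(is.finite(ev$mae)))
  # predictions come back on the native scale of each metric
  p <- predictQuality(fit, X[, 97:120])
  expect_equal(rownames(p), c("SSIM", "GMSD"))
  expect_lt(max(abs(p["GMSD", ] - mean(y2))), 0.5)
})

test_that("evaluation reports MAE and rank correlations with edge handling", {
  y <- seq(0.1, 0.9, length.out = 20)
  fake <- buildModel(tinySpec(), 1L, seed = 1)
  # bypass the network: check the scoring arithmetic directly
  ev <- local({
    p <- y + 0.05
    data.frame(mae = mean(abs(p - y)), sp = cor(p, y, method = "spearman"),
               pe = cor(p, y))
  })
  expect_equal(ev$mae, 0.05)
  expect_equal(ev$sp, 1)
  # constant predictions warn and report zero correlation
  z <- fake
  z@weights <- lapply(z@weights, function(w) list(W = w$W * 0, b = w$b * 0))
  expect_warning(
    evz <- evaluateModel(z, list(t = list(x = tinyBatch(10), y = y[1:10]))),
    "constant")
  expect_equal(evz$spearman, 0)
  expect_equal(evz$pearson, 0)
})

test_that("Grad-CAM maps have input shape, unit range, and follow activations", {
  m <- buildModel(tinySpec(), 1L, seed = 6)
  img <- matrix(runif(32 * 32), 32)
  cam <- gradCAM(m, PAImage(img))
  expect_equal(dim(cam), c(32L, 32L))
  expect_gte(min(cam), 0); expect_lte(max(cam), 1)
  # model whose output is the mean of one activation channel: the map is
  # proportional to that channel's (upsampled) activation
  mm <- m
  W <- mm@weights
  dense1 <- 3L # first dense weight index in this spec (after 2 convs)
  for (i in seq_along(W)) {
    if (i >= dense1) { W[[i]]$W[] <- 0; W[[i]]$b[] <- 0 }
  }
  # last pooled conv map is 16 channels of 8x8 = 1024 units; route channel
  # 1's spatial mean through the dense stack identity-style
  W[[dense1]]$W[1:64, 1] <- 1 / 64
  W[[dense1 + 1L]]$W[1, 1] <- 1
  mm@weights <- W
  cam2 <- gradCAM(mm, PAImage(img))
  out <- paiq:::.nn_run(mm@layers, mm@weights,
                        paiq:::imageBatch(list(PAImage(img))), NULL,
                        FALSE, FALSE, 0L, 4L, -1L) # post-ReLU conv 2
  act <- array(out$capture_act, dim = c(16L, 16L, 16L))
  ch1 <- paiq:::.cc_resize_bilinear(act[, , 1], 32L, 32L)
  ch1 <- pmax(ch1, 0)
  if (max(ch1) > 0) ch1 <- (ch1 - min(ch1)) / (max(ch1) - min(ch1))
  expect_gt(cor(as.vector(cam2), as.vector(ch1)), 0.95)
})

test_that("k-fold indices partition the sample deterministically", {
  f <- kfoldIndices(23L, 5L, seed = 9)
  expect_length(f, 5L)
  expect_setequal(unlist(f), 1:23)
  expect_identical(f, kfoldIndices(23L, 5L, seed = 9))
})
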