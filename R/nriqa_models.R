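# No-reference quality regressors: compact CNNs trained to predict
# full-reference metric scores from a single reconstructed image. The
# forward/backward kernels live in src/nn.cpp; this file defines the
# architectures, label generation, the Adam/MAE training loop with early
# stopping, per-dataset evaluation, and Grad-CAM.

#' Model architecture specifications
#'
#' \code{paqnetSpec}: four conv layers with filter counts 32/64/128/256
#' and kernels 5,3,3,3 (each followed by ReLU and 2x2 max-pool), then two
#' 128-unit dense layers with ReLU and a linear output — about 2.5
#' million parameters at 128x128 input. \code{iqdcnnSpec}: four conv
#' layers of 32 filters (5x5), 2x2 max-pool after each, then three
#' 1024-unit dense layers with ReLU and dropout 0.3 and a linear output.
#'
#' @param kernels per-conv kernel sizes (PAQNet; alternative assignments
#'   of the 5x5/3x3 kernels are selectable).
#' @param filters per-conv filter counts.
#' @param dropout dropout rate on the dense layers (IQDCNN).
#' @param inputSize input image side in pixels.
#' @return an architecture spec list.
#' @name model-specs
NULL

#' @rdname model-specs
#' @export
paqnetSpec <- function(kernels = c(5L, 3L, 3L, 3L),
                       filters = c(32L, 64L, 128L, 256L),
                       inputSize = 128L) {
  stopifnot(length(kernels) == length(filters))
  list(arch = "paqnet", kernels = as.integer(kernels),
       filters = as.integer(filters), dense = c(128L, 128L),
       dropout = 0, inputSize = as.integer(inputSize))
}

#' @rdname model-specs
#' @export
iqdcnnSpec <- function(dropout = 0.3, inputSize = 128L) {
  list(arch = "iqdcnn", kernels = rep(5L, 4L), filters = rep(32L, 4L),
       dense = c(1024L, 1024L, 1024L), dropout = dropout,
       inputSize = as.integer(inputSize))
}

#' Trained quality-regression model
#'
#' @slot spec architecture specification list.
#' @slot layers engine layer list with resolved shapes.
#' @slot weights list of weight arrays.
#' @slot nOutputs number of regression outputs.
#' @slot meta training metadata (target metrics, label scaling, history).
#' @export
setClass("IQAModel",
  representation(spec = "list", layers = "list", weights = "list",
                 nOutputs = "integer", meta = "list"),
  prototype(meta = list()))

setMethod("show", "IQAModel", function(object) {
  cat(sprintf("IQAModel '%s': input 1x%dx%d, %d output(s), %s parameters\n",
              object@spec$arch, object@spec$inputSize,
              object@spec$inputSize, object@nOutputs,
              format(paramCount(object), big.mark = ",")))
  if (!is.null(object@meta$metrics))
    cat("  trained for:", paste(object@meta$metrics, collapse = ", "), "\n")
})

specLayers <- function(spec, nOutputs) {
  H <- spec$inputSize; C <- 1L
  layers <- list()
  for (i in seq_along(spec$filters)) {
    layers <- c(layers, list(
      list(type = "conv", k = spec$kernels[i], C = C, H = H, Wd = H,
           out = spec$filters[i]),
      list(type = "relu"),
      list(type = "pool", C = spec$filters[i], H = H, Wd = H)))
    C <- spec$filters[i]; H <- H %/% 2L
  }
  layers <- c(layers, list(list(type = "flatten")))
  nIn <- C * H * H
  for (u in spec$dense) {
    layers <- c(layers, list(list(type = "dense", "in" = nIn, out = u),
                             list(type = "relu")))
    if (spec$dropout > 0)
      layers <- c(layers, list(list(type = "dropout", rate = spec$dropout)))
    nIn <- u
  }
  c(layers, list(list(type = "dense", "in" = nIn, out = nOutputs)))
}

#' Build a quality-regression model
#'
#' Instantiates the architecture with He-initialized weights; the forward
#' pass maps a batch of 1 x size x size images to \code{nOutputs} reals
#' per image.
#'
#' @param spec \code{\link{paqnetSpec}} or \code{\link{iqdcnnSpec}}.
#' @param nOutputs regression outputs (1 for a single metric; 2 or 5 for
#'   multi-output training).
#' @param seed initialization seed.
#' @return an \linkS4class{IQAModel}.
#' @export
buildModel <- function(spec, nOutputs = 1L, seed = 1L) {
  layers <- specLayers(spec, as.integer(nOutputs))
  nL <- length(layers)
  weights <- withSeed(seed, lapply(seq_len(nL), function(i) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fanIn <- ly$k^2 * ly$C
      W <- array(rnorm(ly$k^2 * ly$C * ly$out, sd = sqrt(2 / fanIn)),
                 dim = c(ly$k, ly$k, ly$C, ly$out))
      list(W = W, b = numeric(ly$out))
    } else if (ly$type == "dense") {
      # regression head starts near zero so initial predictions sit at
      # the (centered) label mean
      scale <- if (i == nL) 0.1 else 1
      W <- matrix(rnorm(ly$`in` * ly$out, sd = scale * sqrt(2 / ly$`in`)),
                  ly$`in`, ly$out)
      list(W = W, b = numeric(ly$out))
    } else NULL
  }))
  weights <- weights[!vapply(weights, is.null, logical(1))]
  new("IQAModel", spec = spec, layers = layers, weights = weights,
      nOutputs = as.integer(nOutputs), meta = list())
}

#' Trainable parameter count of a model
#'
#' @param model an \linkS4class{IQAModel}.
#' @return integer parameter count.
#' @export
paramCount <- function(model) {
  sum(vapply(model@weights,
             function(w) length(w$W) + length(w$b), numeric(1)))
}

# stack images (PAImage list or matrix list) into an engine batch D x N
imageBatch <- function(images) {
  mats <- lapply(images, function(im) {
    m <- if (is(im, "PAImage")) pixels(im) / dataRange(im) else im
    as.vector(m)
  })
  do.call(cbind, mats)
}

#' Forward-pass predictions
#'
#' @param model an \linkS4class{IQAModel}.
#' @param images list of \linkS4class{PAImage}/matrices, or a D x N batch
#'   matrix.
#' @param denormalize map outputs back to native metric scale using the
#'   label scaling stored at training time (multi-output models).
#' @return numeric matrix nOutputs x N.
#' @export
predictQuality <- function(model, images, denormalize = TRUE) {
  X <- if (is.matrix(images)) images else imageBatch(images)
  preds <- lapply(seq(1L, ncol(X), by = 256L), function(s) {
    e <- min(s + 255L, ncol(X))
    .nn_run(model@layers, model@weights, X[, s:e, drop = FALSE], NULL,
            FALSE, FALSE, 0L, -1L, -1L)$pred
  })
  out <- list(pred = do.call(cbind, preds))
  pred <- matrix(out$pred, nrow = model@nOutputs)
  sc <- model@meta$scaling
  if (denormalize && !is.null(sc)) {
    for (i in seq_len(nrow(pred)))
      pred[i, ] <- ((pred[i, ] + 0.5) * (sc$hi[i] - sc$lo[i]) + sc$lo[i]) *
        sc$sign[i]
  }
  rownames(pred) <- model@meta$metrics
  pred
}

#' Training configuration
#'
#' Defaults mirror the study protocol: MAE loss, Adam with learning rate
#' 1e-4, batches of 16, early stopping on validation loss, K = 5 folds
#' for hyperparameter cross-validation.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience in epochs (0 stops at the
#'   first non-improving validation epoch).
#' @param seed RNG seed for shuffling and dropout.
#' @param kFolds folds for \code{\link{kfoldIndices}}.
#' @return config list.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 16L,
                        maxEpochs = 20L, patience = 10L, seed = 1L,
                        kFolds = 5L) {
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed), kFolds = as.integer(kFolds))
}

#' K-fold split indices
#'
#' @param n number of samples.
#' @param k folds.
#' @param seed shuffle seed.
#' @return list of k disjoint index vectors covering 1..n.
#' @export
kfoldIndices <- function(n, k = 5L, seed = 1L) {
  idx <- withSeed(seed, sample.int(n))
  split(idx, rep_len(seq_len(k), n))
}

#' Metric labels for a manifest
#'
#' Computes the chosen full-reference metric value(s) of every test image
#' against its reference — the "ground truth" quality scores used to
#' supervise the regressors. Images failing a metric are excluded with a
#' warning.
#'
#' @param manifest a \linkS4class{LadderManifest}.
#' @param metrics character vector of \code{\link{frMetrics}} names.
#' @param configs \code{\link{frConfigs}}.
#' @return data.frame with \code{path_test}, \code{subset},
#'   \code{quality_rank}, and one column per metric.
#' @export
labelDataset <- function(manifest, metrics = "SSIM",
                         configs = frConfigs()) {
  rec <- manifest@records
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    ok <- tryCatch({
      ref <- normalizeMinmax(loadImage(rec$path_reference[i]))
      tst <- normalizeMinmax(loadImage(rec$path_test[i]))
      df <- computeAllFR(validatePair(ref, tst), configs, metrics)
      vals <- setNames(as.list(df$value), df$metric)
      c(list(path_test = rec$path_test[i], subset = rec$subset[i],
             quality_rank = rec$quality_rank[i]), vals)
    }, error = function(e) {
      warning("excluding ", rec$path_test[i], ": ", conditionMessage(e))
      NULL
    })
    ok
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  do.call(rbind, lapply(rows, as.data.frame))
}

lowerBetter <- function(metric) metric %in% c("GMSD", "MS-GMSD")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a quality-regression model
#'
#' MAE loss, Adam, shuffled minibatches, early stopping on validation
#' MAE; the best-validation checkpoint is returned. For multi-output
#' models the labels are min-max normalized per metric over the training
#' split (lower-is-better metrics are negated first so every head is
#' higher-is-better internally) and the joint loss is the unweighted mean
#' of the per-metric MAEs; the scaling is stored for de-normalization.
#'
#' @param model an \linkS4class{IQAModel}.
#' @param trainX,valX image batches (D x N matrices or image lists).
#' @param trainY,valY numeric matrices N x nOutputs (or vectors) of raw
#'   metric values, columns named by metric.
#' @param cfg \code{\link{trainConfig}}.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{IQAModel}; training history in
#'   \code{meta$history}.
#' @export
trainModel <- function(model, trainX, trainY, valX, valY,
                       cfg = trainConfig(), verbose = FALSE) {
  X <- if (is.matrix(trainX)) trainX else imageBatch(trainX)
  Xv <- if (is.matrix(valX)) valX else imageBatch(valX)
  Y <- rbind(t(as.matrix(trainY)))
  Yv <- rbind(t(as.matrix(valY)))
  if (nrow(Y) != model@nOutputs)
    stop("label columns (", nrow(Y), ") do not match model outputs (",
         model@nOutputs, ")")
  if (ncol(X) != ncol(Y) || ncol(Xv) != ncol(Yv))
    stop("image/label count mismatch")
  metrics <- rownames(Y) %||% model@meta$metrics %||%
    paste0("out", seq_len(model@nOutputs))
  # internal label scale: lower-better heads negated, per-metric min-max
  # normalization (multi-output) or unit scale (single output), centered
  # so an untrained (zero-output) model starts at the training mean
  sign <- ifelse(lowerBetter(metrics), -1, 1)
  Ys <- Y * sign
  if (model@nOutputs > 1L) {
    lo <- apply(Ys, 1L, min); hi <- apply(Ys, 1L, max)
    hi[hi <= lo] <- lo[hi <= lo] + 1
  } else {
    mu <- mean(Ys)
    lo <- mu - 0.5; hi <- mu + 0.5
  }
  Y <- (Ys - lo) / (hi - lo) - 0.5
  Yv <- (Yv * sign - lo) / (hi - lo) - 0.5
  sc <- list(lo = lo, hi = hi, sign = sign)
  fit <- .nn_train(model@layers, model@weights, X, Y, Xv, Yv,
                   cfg$learningRate, cfg$batchSize, cfg$maxEpochs,
                   cfg$patience, cfg$seed)
  history <- data.frame(epoch = seq_along(fit$train_mae),
                        train_mae = fit$train_mae,
                        val_mae = fit$val_mae)
  if (verbose)
    for (i in seq_len(nrow(history)))
      message(sprintf("epoch %d: train %.5f val %.5f", i,
                      history$train_mae[i], history$val_mae[i]))
  model@weights <- fit$weights
  model@meta <- c(model@meta[setdiff(names(model@meta),
                                     c("history", "scaling", "metrics"))],
                  list(history = history, scaling = sc, metrics = metrics,
                       bestEpoch = fit$best_epoch))
  model
}

#' Evaluate a model on one or more test sets
#'
#' Per dataset and per target metric: mean absolute error, Spearman rho
#' and Pearson r between predictions (de-normalized to native metric
#' scale) and true values. Constant predictions yield correlation 0 with
#' a warning.
#'
#' @param model a trained \linkS4class{IQAModel}.
#' @param testSets named list; each element is
#'   \code{list(x = batch, y = labels)}.
#' @return data.frame with columns \code{dataset}, \code{metric},
#'   \code{mae}, \code{spearman}, \code{pearson}, \code{n}.
#' @export
evaluateModel <- function(model, testSets) {
  metrics <- model@meta$metrics %||% paste0("out", seq_len(model@nOutputs))
  rows <- list()
  for (ds in names(testSets)) {
    s <- testSets[[ds]]
    pred <- predictQuality(model, s$x)
    truth <- rbind(t(as.matrix(s$y)))
    for (i in seq_len(model@nOutputs)) {
      p <- pred[i, ]; y <- truth[i, ]
      rho <- r <- 0
      if (sd(p) == 0 || sd(y) == 0) {
        warning("constant predictions or labels for ", metrics[i], " on ",
                ds, "; correlations reported as 0")
      } else {
        rho <- cor(p, y, method = "spearman")
        r <- cor(p, y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, metric = metrics[i], mae = mean(abs(p - y)),
        spearman = rho, pearson = r, n = length(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grad-CAM saliency map
#'
#' Channel weights are the spatial means of the selected output's
#' gradient at the final convolutional layer's (post-ReLU) activations;
#' the map is the ReLU of the weighted activation sum, bilinearly
#' upsampled to the input size and min-max normalized to [0, 1]. An
#' all-zero map is returned as zeros with a warning.
#'
#' @param model an \linkS4class{IQAModel}.
#' @param img a \linkS4class{PAImage} (or matrix) at the model input size.
#' @param outputIndex 1-based output to explain.
#' @return numeric matrix (input size) in [0, 1].
#' @export
gradCAM <- function(model, img, outputIndex = 1L) {
  convPos <- which(vapply(model@layers, function(l) l$type == "conv",
                          logical(1)))
  last <- max(convPos)
  # capture after the ReLU that follows the last conv
  cap <- if (model@layers[[last + 1L]]$type == "relu") last + 1L else last
  ly <- model@layers[[last]]
  C <- ly$out; H <- ly$H; W <- ly$Wd
  X <- imageBatch(list(img))
  out <- .nn_run(model@layers, model@weights, X, NULL, FALSE, FALSE, 0L,
                 cap - 1L, outputIndex - 1L)
  act <- array(out$capture_act, dim = c(H, W, C))
  grad <- array(out$capture_grad, dim = c(H, W, C))
  alpha <- apply(grad, 3L, mean)
  cam <- matrix(0, H, W)
  for (k in seq_len(C)) cam <- cam + alpha[k] * act[, , k]
  cam[cam < 0] <- 0
  size <- model@spec$inputSize
  cam <- resizeBilinear(cam, size, size)
  if (max(cam) <= 0) {
    warning("all-zero Grad-CAM map")
    return(matrix(0, size, size))
  }
  (cam - min(cam)) / (max(cam) - min(cam))
}
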