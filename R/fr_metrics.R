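# Full-reference metrics. All operate on a validated PAImagePair whose two
# images share shape and data range; scores follow each metric's published
# formulation with constants defined on the 0-255 scale rescaled by
# (R/255)^2 so normalized [0,1] images reproduce 8-bit behavior.

#' Full-reference metric configurations
#'
#' Constructors for the tunable parameter sets of the SSIM family and the
#' remaining full-reference metrics. Defaults follow the original
#' publications where the underlying method leaves them open.
#'
#' @param K1,K2 SSIM stabilizer factors; \code{C1=(K1*R)^2, C2=(K2*R)^2}.
#' @param windowSize,windowSigma Gaussian weighting window (11, 1.5).
#' @param scales number of dyadic scales.
#' @param weights per-scale exponents (standard five-scale values).
#' @param offset sensitivity of the structure mask threshold.
#' @param thresholdScale fraction of the data range multiplied by
#'   \code{offset} to shift the local-mean threshold.
#' @param c gradient-similarity stabilizer (170/255^2 at data range 1).
#' @param varianceMode report variance instead of standard deviation.
#' @param sigmaNsq visual-noise variance on the 0-255 scale.
#' @param window side of the uniform sliding window.
#' @param epsilon denominator stabilizer.
#' @param T1,T2 phase-congruency / gradient stabilizers.
#' @param alpha,beta exponents of the two similarity components
#'   (\code{fsimConfig}), or logistic steepness (\code{haarpsiConfig}).
#' @param levels Haar decomposition levels / pyramid levels.
#' @param C Haar-band similarity constant on the 0-255 scale.
#' @param subsample 2x2 mean-pool preprocessing (canonical HaarPSI).
#' @param sigmaN sensory noise standard deviation as a fraction of R.
#' @name fr-configs
NULL

#' @rdname fr-configs
#' @export
ssimConfig <- function(K1 = 0.01, K2 = 0.03, windowSize = 11L,
                       windowSigma = 1.5) {
  stopifnot(K1 > 0, K2 > 0, windowSize %% 2L == 1L)
  list(K1 = K1, K2 = K2, windowSize = as.integer(windowSize),
       windowSigma = windowSigma)
}

#' @rdname fr-configs
#' @export
msssimConfig <- function(scales = 5L,
                         weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  stopifnot(scales >= 1L, all(weights > 0), length(weights) >= scales)
  list(scales = as.integer(scales), weights = weights)
}

#' @rdname fr-configs
#' @export
s3imConfig <- function(offset = 0.5, thresholdScale = 0.1) {
  list(offset = offset, thresholdScale = thresholdScale)
}

#' @rdname fr-configs
#' @export
gmsdConfig <- function(c = 170 / 255^2, scales = 4L, varianceMode = FALSE) {
  stopifnot(c > 0)
  list(c = c, scales = as.integer(scales), varianceMode = varianceMode)
}

#' @rdname fr-configs
#' @export
vifConfig <- function(sigmaNsq = 2, window = 9L) {
  stopifnot(sigmaNsq > 0)
  list(sigmaNsq = sigmaNsq, window = as.integer(window))
}

#' @rdname fr-configs
#' @export
uqiConfig <- function(window = 8L, epsilon = 1e-12) {
  stopifnot(window >= 2L)
  list(window = as.integer(window), epsilon = epsilon)
}

#' @rdname fr-configs
#' @export
fsimConfig <- function(alpha = 1, beta = 1, T1 = 0.85, T2 = 160 / 255^2) {
  stopifnot(T1 > 0, T2 > 0)
  list(alpha = alpha, beta = beta, T1 = T1, T2 = T2)
}

#' @rdname fr-configs
#' @export
haarpsiConfig <- function(levels = 3L, C = 30 / 255^2, alpha = 4.2,
                          subsample = TRUE) {
  stopifnot(C > 0, alpha > 0)
  list(levels = as.integer(levels), C = C, alpha = alpha,
       subsample = subsample)
}

#' @rdname fr-configs
#' @export
iwssimConfig <- function(levels = 5L, sigmaN = 0.03,
                         weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  stopifnot(levels >= 2L)
  list(levels = as.integer(levels), sigmaN = sigmaN, weights = weights)
}

metricResult <- function(metric, value, higherIsBetter, details = list()) {
  new("MetricResult", metric = metric, value = value,
      higherIsBetter = higherIsBetter, details = details)
}

pairMatrices <- function(pair) {
  list(x = pixels(pair@reference), y = pixels(pair@test),
       R = dataRange(pair@reference))
}

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(R^2 / MSE)} in dB; identical images give \code{+Inf}.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @return a \linkS4class{MetricResult} (higher is better).
#' @export
psnr <- function(pair) {
  p <- pairMatrices(pair)
  mse <- mean((p$x - p$y)^2)
  v <- if (mse == 0) Inf else 10 * log10(p$R^2 / mse)
  metricResult("PSNR", v, TRUE, list(mse = mse))
}

# SSIM map machinery: returns full map plus luminance and
# contrast-structure components over the valid window region
ssimMaps <- function(x, y, R, cfg) {
  if (min(dim(x)) < cfg$windowSize)
    stop("image smaller than the SSIM window")
  K <- gaussianKernel(cfg$windowSize, cfg$windowSigma)
  C1 <- (cfg$K1 * R)^2; C2 <- (cfg$K2 * R)^2
  m <- localMoments(x, y, K)
  l <- (2 * m$mx * m$my + C1) / (m$mx^2 + m$my^2 + C1)
  cs <- (2 * m$sxy + C2) / (m$sxx + m$syy + C2)
  list(map = l * cs, l = l, cs = cs)
}

#' Structural similarity index
#'
#' Mean of the Gaussian-windowed SSIM map (11x11, sigma 1.5, valid-region
#' convolution). The per-pixel map is available in \code{details$map}.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{ssimConfig}}.
#' @return a \linkS4class{MetricResult} in [-1, 1]; higher is better.
#' @export
ssim <- function(pair, cfg = ssimConfig()) {
  p <- pairMatrices(pair)
  s <- ssimMaps(p$x, p$y, p$R, cfg)
  metricResult("SSIM", mean(s$map), TRUE, list(map = s$map))
}

#' Multi-scale structural similarity
#'
#' Product over dyadic scales of mean contrast-structure terms, with the
#' full SSIM (luminance included) at the coarsest scale, each raised to
#' the standard five-scale exponents. Downsampling is 2x2 mean pooling.
#' The scale count is reduced (with a warning) when the image is too
#' small for the requested pyramid.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{msssimConfig}}.
#' @param ssimCfg \code{\link{ssimConfig}}.
#' @return a \linkS4class{MetricResult}; higher is better.
#' @export
msSSIM <- function(pair, cfg = msssimConfig(), ssimCfg = ssimConfig()) {
  p <- pairMatrices(pair)
  M <- cfg$scales
  while (M > 1L && floor(min(dim(p$x)) / 2^(M - 1)) < ssimCfg$windowSize) {
    M <- M - 1L
    warning("image too small for requested scales; reduced to ", M)
  }
  w <- if (M == length(cfg$weights)) cfg$weights
       else cfg$weights[seq_len(M)] / sum(cfg$weights[seq_len(M)])
  if (M == 1L) w <- 1
  x <- p$x; y <- p$y
  val <- 1
  for (j in seq_len(M)) {
    s <- ssimMaps(x, y, p$R, ssimCfg)
    term <- if (j < M) mean(s$cs) else mean(s$map)
    val <- val * max(term, 0)^w[j]
    if (j < M) { x <- meanPool2(x); y <- meanPool2(y) }
  }
  metricResult("MS-SSIM", val, TRUE)
}

#' Gradient magnitude similarity deviation
#'
#' Prewitt gradient magnitudes of both images (after a 2x2 mean-pool
#' prefilter), pixel-wise similarity
#' \code{(2 Gx Gy + c) / (Gx^2 + Gy^2 + c)}, scored by the population
#' standard deviation of the similarity map. Identical images give 0.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{gmsdConfig}}.
#' @return a \linkS4class{MetricResult}; lower is better.
#' @export
gmsd <- function(pair, cfg = gmsdConfig()) {
  p <- pairMatrices(pair)
  v <- gmsdValue(p$x, p$y, p$R, cfg)
  metricResult("GMSD", v, FALSE)
}

gmsdValue <- function(x, y, R, cfg) {
  x <- meanPool2(x); y <- meanPool2(y)
  hx <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3, 3) # Prewitt rows
  hy <- t(hx)
  gx <- sqrt(filt2(x, hx, "same", "symmetric")^2 +
             filt2(x, hy, "same", "symmetric")^2)
  gy <- sqrt(filt2(y, hx, "same", "symmetric")^2 +
             filt2(y, hy, "same", "symmetric")^2)
  c0 <- cfg$c * R^2
  sim <- (2 * gx * gy + c0) / (gx^2 + gy^2 + c0)
  v <- mean((sim - mean(sim))^2) # population variance
  if (cfg$varianceMode) v else sqrt(v)
}

#' Multi-scale gradient magnitude similarity deviation
#'
#' Root-mean-square of per-scale GMSD values over a dyadic mean-pool
#' pyramid with equal scale weights.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{gmsdConfig}} (field \code{scales}).
#' @return a \linkS4class{MetricResult}; lower is better.
#' @export
msGMSD <- function(pair, cfg = gmsdConfig()) {
  p <- pairMatrices(pair)
  M <- cfg$scales
  while (M > 1L && floor(min(dim(p$x)) / 2^(M - 1)) < 8L) {
    M <- M - 1L
    warning("image too small for requested scales; reduced to ", M)
  }
  x <- p$x; y <- p$y
  vals <- numeric(M)
  for (j in seq_len(M)) {
    vals[j] <- gmsdValue(x, y, p$R, cfg)
    if (j < M) { x <- meanPool2(x); y <- meanPool2(y) }
  }
  metricResult("MS-GMSD", sqrt(mean(vals^2)), FALSE,
               list(perScale = vals))
}

#' Pixel-domain visual information fidelity
#'
#' The simplified spatial-domain information ratio
#' \code{sum(g * log(1 + s2/sn2)) / sum(log(1 + s2/sn2))} with local gain
#' \code{g = cov(x,y)/var(x)} and reference signal variance \code{s2}
#' estimated over uniform 9x9 windows; \code{sn2} defaults to 2 on the
#' 0-255 scale and is rescaled by \code{(R/255)^2}. Identical images give
#' 1; an all-constant reference is degenerate and errors.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{vifConfig}}.
#' @return a \linkS4class{MetricResult}; higher is better.
#' @export
vifP <- function(pair, cfg = vifConfig()) {
  p <- pairMatrices(pair)
  if (stats::var(as.vector(p$x)) == 0)
    stop("VIF undefined for an all-constant reference image")
  K <- matrix(1 / cfg$window^2, cfg$window, cfg$window)
  m <- localMoments(p$x, p$y, K)
  eps <- 1e-10
  g <- m$sxy / (m$sxx + eps)
  g[g < 0] <- 0
  sn2 <- cfg$sigmaNsq * (p$R / 255)^2
  info <- log(1 + m$sxx / sn2)
  metricResult("VIF", sum(g * info) / sum(info), TRUE)
}

#' Universal image quality index
#'
#' Mean over uniform sliding windows of
#' \code{4 mx my sxy / ((mx^2 + my^2 + eps)(sx2 + sy2 + eps))}.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{uqiConfig}}.
#' @return a \linkS4class{MetricResult} in [-1, 1]; higher is better.
#' @export
uqi <- function(pair, cfg = uqiConfig()) {
  p <- pairMatrices(pair)
  if (min(dim(p$x)) < cfg$window) stop("image smaller than the UQI window")
  K <- matrix(1 / cfg$window^2, cfg$window, cfg$window)
  m <- localMoments(p$x, p$y, K)
  q <- (4 * m$mx * m$my * m$sxy) /
       ((m$mx^2 + m$my^2 + cfg$epsilon) * (m$sxx + m$syy + cfg$epsilon))
  metricResult("UQI", mean(q), TRUE)
}
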