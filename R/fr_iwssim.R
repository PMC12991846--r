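# Information-content-weighted multiscale SSIM. Local contrast-structure
# scores are averaged with weights equal to the information the visual
# system receives about the scene from reference and distorted image
# under a Gaussian scale-mixture source model with channel distortion
# d = g c + v and additive sensory noise.

# information-content weight map from a band pair (3x3 uniform windows)
iwInfoWeights <- function(cx, cy, sigmaNsq) {
  K <- matrix(1 / 9, 3, 3)
  m <- localMoments(cx, cy, K)
  eps <- 1e-10
  g <- m$sxy / (m$sxx + eps)
  vv <- m$syy - g * m$sxy
  g[m$sxx < eps] <- 0
  vv[m$sxx < eps] <- m$syy[m$sxx < eps]
  vv[vv < eps] <- eps
  log2((1 + m$sxx / sigmaNsq) * (1 + g^2 * m$sxx / (vv + sigmaNsq)))
}

# crop a matrix symmetrically to the given dimensions
cropCenter <- function(m, h, w) {
  dr <- nrow(m) - h; dc <- ncol(m) - w
  r0 <- floor(dr / 2); c0 <- floor(dc / 2)
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
}

#' Information-weighted multiscale SSIM (IW-SSIM)
#'
#' A mean-pool Gaussian pyramid (the same downsampler as
#' \code{\link{msSSIM}}) is built for both images; at each of the finer
#' scales the contrast-structure SSIM component is averaged with
#' information-content weights computed from the scale's Laplacian band
#' (band minus the bilinearly upsampled next level); the coarsest scale
#' uses the full SSIM map weighted by the information content of the
#' low-pass residual. Per-scale results are combined with the standard
#' five-scale exponents. With \code{uniformWeights = TRUE} the weighting
#' degenerates and the score equals \code{\link{msSSIM}}.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{iwssimConfig}}; \code{sigmaN} is the sensory
#'   noise sd as a fraction of the data range (0.03).
#' @param ssimCfg \code{\link{ssimConfig}}.
#' @param uniformWeights force uniform information weights.
#' @return a \linkS4class{MetricResult}; higher is better.
#' @export
iwSSIM <- function(pair, cfg = iwssimConfig(), ssimCfg = ssimConfig(),
                   uniformWeights = FALSE) {
  p <- pairMatrices(pair)
  M <- cfg$levels
  while (M > 1L && floor(min(dim(p$x)) / 2^(M - 1)) < ssimCfg$windowSize) {
    M <- M - 1L
    warning("image too small for requested levels; reduced to ", M)
  }
  w <- if (M == length(cfg$weights)) cfg$weights
       else cfg$weights[seq_len(M)] / sum(cfg$weights[seq_len(M)])
  if (M == 1L) w <- 1
  sigmaNsq <- (cfg$sigmaN * p$R)^2
  x <- p$x; y <- p$y
  val <- 1
  for (j in seq_len(M)) {
    s <- ssimMaps(x, y, p$R, ssimCfg)
    band <- if (j < M) {
      xd <- meanPool2(x); yd <- meanPool2(y)
      list(x = x - resizeBilinear(xd, nrow(x), ncol(x)),
           y = y - resizeBilinear(yd, nrow(y), ncol(y)))
    } else list(x = x, y = y)
    score <- if (j < M) s$cs else s$map
    if (uniformWeights) {
      term <- mean(score)
    } else {
      iw <- iwInfoWeights(band$x, band$y, sigmaNsq)
      iw <- cropCenter(iw, nrow(score), ncol(score))
      iw <- pmax(iw, 0)
      term <- if (sum(iw) > 0) sum(score * iw) / sum(iw) else mean(score)
    }
    val <- val * max(term, 0)^w[j]
    if (j < M) { x <- xd; y <- yd }
  }
  metricResult("IW-SSIM", val, TRUE)
}
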