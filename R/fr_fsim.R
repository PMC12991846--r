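# Feature similarity index: phase congruency (log-Gabor filter bank)
# combined with Scharr gradient magnitude similarity, pooled with the
# pointwise maximum phase congruency as weight.

# Kovesi-style phase congruency map: 4 log-Gabor scales x 4 orientations,
# Rayleigh noise threshold, frequency-spread weighting.
phaseCongruency <- function(m, nscale = 4L, norient = 4L,
                            minWavelength = 6, mult = 2, sigmaOnf = 0.55,
                            dThetaOnSigma = 1.2, k = 2.0, eps = 1e-4,
                            cutoff = 0.5, g = 10) {
  H <- nrow(m); W <- ncol(m)
  IM <- stats::fft(m)
  fx <- ifelse(seq_len(W) - 1 <= W / 2, seq_len(W) - 1, seq_len(W) - 1 - W) / W
  fy <- ifelse(seq_len(H) - 1 <= H / 2, seq_len(H) - 1, seq_len(H) - 1 - H) / H
  X <- matrix(fx, H, W, byrow = TRUE)
  Y <- matrix(fy, H, W)
  radius <- sqrt(X^2 + Y^2)
  radius[1, 1] <- 1
  theta <- atan2(-Y, X)
  lowpass <- 1 / (1 + (radius / 0.45)^(2 * 15))
  logGabor <- lapply(seq_len(nscale), function(s) {
    fo <- 1 / (minWavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigmaOnf)^2)) * lowpass
    lg[1, 1] <- 0
    lg
  })
  thetaSigma <- pi / norient / dThetaOnSigma
  pcSum <- matrix(0, H, W)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sin(theta) * cos(angl) - cos(theta) * sin(angl)
    dc <- cos(theta) * cos(angl) + sin(theta) * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
    sumE <- matrix(0, H, W); sumO <- matrix(0, H, W)
    sumAn <- matrix(0, H, W); maxAn <- matrix(0, H, W)
    eList <- vector("list", nscale); oList <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- logGabor[[s]] * spread
      EO <- stats::fft(IM * filt, inverse = TRUE) / (H * W)
      e <- Re(EO); od <- Im(EO)
      An <- sqrt(e^2 + od^2)
      sumE <- sumE + e; sumO <- sumO + od
      sumAn <- sumAn + An; maxAn <- pmax(maxAn, An)
      eList[[s]] <- e; oList[[s]] <- od
      if (s == 1L) tau <- stats::median(An) / sqrt(log(4))
    }
    xEnergy <- sqrt(sumE^2 + sumO^2) + eps
    meanE <- sumE / xEnergy; meanO <- sumO / xEnergy
    energy <- matrix(0, H, W)
    for (s in seq_len(nscale)) {
      e <- eList[[s]]; od <- oList[[s]]
      energy <- energy + e * meanE + od * meanO - abs(e * meanO - od * meanE)
    }
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    energy <- pmax(energy - (noiseMean + k * noiseSigma), 0)
    width <- (sumAn / (maxAn + eps) - 1) / (nscale - 1)
    weight <- 1 / (1 + exp(g * (cutoff - width)))
    pcSum <- pcSum + weight * energy / (sumAn + eps)
  }
  pcSum
}

#' Feature similarity index (FSIM)
#'
#' \code{S_L = S_PC^alpha * S_G^beta} where \code{S_PC} is the similarity
#' of the two phase congruency maps (stabilizer \code{T1}) and \code{S_G}
#' the similarity of Scharr gradient magnitudes (stabilizer \code{T2},
#' defined on the 0-255 scale and rescaled by \code{(R/255)^2}), pooled
#' as the \code{max(PC1, PC2)}-weighted mean. Images larger than 256 px
#' on the short side are pre-averaged and decimated per the original
#' protocol.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{fsimConfig}}.
#' @return a \linkS4class{MetricResult} in [0, 1]; higher is better.
#' @export
fsim <- function(pair, cfg = fsimConfig()) {
  p <- pairMatrices(pair)
  x <- p$x; y <- p$y
  f <- max(1, round(min(dim(x)) / 256))
  if (f > 1) {
    K <- matrix(1 / f^2, f, f)
    x <- filt2(x, K, "same", "symmetric")[seq(1, nrow(x), f),
                                          seq(1, ncol(x), f)]
    y <- filt2(y, K, "same", "symmetric")[seq(1, nrow(y), f),
                                          seq(1, ncol(y), f)]
  }
  pc1 <- phaseCongruency(x)
  pc2 <- phaseCongruency(y)
  scharrX <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3) / 16, 3, 3)
  g1 <- sqrt(filt2(x, scharrX, "same", "zero")^2 +
             filt2(x, t(scharrX), "same", "zero")^2)
  g2 <- sqrt(filt2(y, scharrX, "same", "zero")^2 +
             filt2(y, t(scharrX), "same", "zero")^2)
  T2 <- cfg$T2 * p$R^2
  sPC <- (2 * pc1 * pc2 + cfg$T1) / (pc1^2 + pc2^2 + cfg$T1)
  sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  sL <- sPC^cfg$alpha * sG^cfg$beta
  pcm <- pmax(pc1, pc2)
  if (sum(pcm) == 0) { # no salient structure in either image
    return(metricResult("FSIM", mean(sL), TRUE))
  }
  metricResult("FSIM", sum(sL * pcm) / sum(pcm), TRUE,
               list(sPC = sPC, sG = sG, pcMax = pcm))
}
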