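# Sparse masked SSIM: structural similarity restricted to adaptively
# detected structure regions, suppressing the noise-dominated background
# that fills most of a photoacoustic frame.

#' Adaptive structure mask
#'
#' Gaussian local thresholding: a pixel belongs to the mask iff its
#' intensity exceeds its Gaussian-weighted neighborhood mean by
#' \code{offset * thresholdScale * R}. The neighborhood size follows the
#' resolution rule \code{floor(H/16)*2 + 1} (H = image height), forced
#' odd and at least 3. A constant image has no pixel above its shifted
#' local mean and yields an empty mask.
#'
#' @param img a \linkS4class{PAImage}.
#' @param cfg \code{\link{s3imConfig}}.
#' @return logical matrix, \code{TRUE} on structure.
#' @export
s3imMask <- function(img, cfg = s3imConfig()) {
  m <- pixels(img)
  n <- s3imNeighborhood(nrow(m))
  K <- gaussianKernel(n, adaptiveSigma(n))
  localMean <- filt2(m, K, "same", "symmetric")
  m > localMean + cfg$offset * cfg$thresholdScale * dataRange(img)
}

s3imNeighborhood <- function(H) {
  n <- floor(H / 16) * 2 + 1
  max(as.integer(n), 3L)
}

#' Sparse masked structural similarity (S3IM)
#'
#' Three steps: (1) adaptive structure masks of reference and test image
#' (\code{\link{s3imMask}}); (2) the masks are OR-combined and applied to
#' both images, zeroing background; (3) the SSIM map of the masked images
#' is averaged over the masked region only:
#' \code{sum(map * mask) / sum(mask)}. If neither image has structure the
#' score is 1 with a warning (both images are structureless, hence
#' indistinguishable), so ladders containing blank frames don't abort.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{s3imConfig}}.
#' @param ssimCfg \code{\link{ssimConfig}}.
#' @param mask optional logical matrix overriding the combined mask.
#' @return a \linkS4class{MetricResult}; higher is better.
#' @export
s3im <- function(pair, cfg = s3imConfig(), ssimCfg = ssimConfig(),
                 mask = NULL) {
  p <- pairMatrices(pair)
  if (is.null(mask)) {
    mask <- s3imMask(pair@reference, cfg) | s3imMask(pair@test, cfg)
  }
  storage.mode(mask) <- "logical"
  xm <- p$x * mask
  ym <- p$y * mask
  s <- ssimMaps(xm, ym, p$R, ssimCfg)
  b <- (ssimCfg$windowSize - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  maskValid <- mask[(b + 1):(H - b), (b + 1):(W - b), drop = FALSE]
  n <- sum(maskValid)
  if (n == 0) {
    warning("empty structure mask: both images structureless; S3IM = 1")
    return(metricResult("S3IM", 1.0, TRUE, list(mask = mask)))
  }
  metricResult("S3IM", sum(s$map * maskValid) / n, TRUE,
               list(mask = mask))
}
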