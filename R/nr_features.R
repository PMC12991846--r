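# BRISQUE natural-scene-statistics feature chain: MSCN normalization,
# directional pairwise products, and GGD/AGGD moment-matching fits up to
# the 36-dimensional feature vector. The final score of the original
# method needs an SVM trained on human-labeled natural images; that
# scorer is intentionally not shipped — plug an external model onto the
# feature vector if scores are needed.

#' Mean-subtracted contrast-normalized (MSCN) coefficients
#'
#' \code{Ihat = (I - mu) / (sigma + C)} with \code{mu}, \code{sigma} from
#' Gaussian-weighted local moments (7x7 window, sigma 7/6, symmetric
#' boundary) and \code{C} a small stabilizer (1/255 of the data range).
#'
#' @param img a \linkS4class{PAImage}.
#' @param windowSize,windowSigma local moment window (7, 7/6).
#' @param C stabilizing constant; default \code{dataRange/255}.
#' @return list with matrices \code{coefficients}, \code{localMean},
#'   \code{localSd}, and the constant \code{C}.
#' @export
mscn <- function(img, windowSize = 7L, windowSigma = 7 / 6, C = NULL) {
  m <- pixels(img)
  if (is.null(C)) C <- dataRange(img) / 255
  K <- gaussianKernel(windowSize, windowSigma)
  mu <- filt2(m, K, "same", "symmetric")
  sig <- sqrt(pmax(filt2(m * m, K, "same", "symmetric") - mu^2, 0))
  list(coefficients = (m - mu) / (sig + C), localMean = mu, localSd = sig,
       C = C)
}

#' Directional pairwise products of MSCN coefficients
#'
#' The four shifted-neighbor products: horizontal
#' \code{I(i,j) I(i,j+1)}, vertical \code{I(i,j) I(i+1,j)}, main diagonal
#' \code{I(i,j) I(i+1,j+1)} and secondary diagonal
#' \code{I(i,j) I(i+1,j-1)}; each grid is one row/column smaller in the
#' shifted direction.
#'
#' @param field matrix of MSCN coefficients (or the list from
#'   \code{\link{mscn}}).
#' @return list of matrices \code{H}, \code{V}, \code{D1}, \code{D2}.
#' @export
pairwiseProducts <- function(field) {
  if (is.list(field)) field <- field$coefficients
  h <- nrow(field); w <- ncol(field)
  stopifnot(h >= 2L, w >= 2L)
  list(H = field[, -w, drop = FALSE] * field[, -1, drop = FALSE],
       V = field[-h, , drop = FALSE] * field[-1, , drop = FALSE],
       D1 = field[-h, -w, drop = FALSE] * field[-1, -1, drop = FALSE],
       D2 = field[-h, -1, drop = FALSE] * field[-1, -w, drop = FALSE])
}

# gamma-ratio function rho(beta) = Gamma(1/b)Gamma(3/b)/Gamma(2/b)^2,
# decreasing in b; inverted on [0.2, 10] by root finding
ggdRho <- function(b) {
  exp(lgamma(1 / b) + lgamma(3 / b) - 2 * lgamma(2 / b))
}

invertMomentRatio <- function(target, lo = 0.2, hi = 10) {
  if (target >= ggdRho(lo)) return(lo)
  if (target <= ggdRho(hi)) return(hi)
  uniroot(function(b) ggdRho(b) - target, c(lo, hi), tol = 1e-8)$root
}

#' Fit a generalized Gaussian distribution by moment matching
#'
#' Shape solved from the ratio \code{E[x^2]/E[|x|]^2} via the standard
#' gamma-function inversion, clamped to [0.2, 10]; variance is the raw
#' second moment.
#'
#' @param samples numeric vector (>= 100 values).
#' @return list with \code{shape} and \code{variance}.
#' @export
fitGGD <- function(samples) {
  samples <- samples[is.finite(samples)]
  stopifnot(length(samples) >= 100L)
  m2 <- mean(samples^2)
  m1 <- mean(abs(samples))
  if (m2 == 0 || m1 == 0) stop("degenerate fit: all-zero samples")
  list(shape = invertMomentRatio(m2 / m1^2), variance = m2)
}

#' Fit an asymmetric generalized Gaussian distribution
#'
#' Moment matching on the side-split second moments (Mittal et al.
#' estimator): shape from the generalized ratio using the left/right
#' standard deviations, mean from the fitted gamma-moment relation.
#'
#' @param samples numeric vector (>= 100 values).
#' @return list with \code{shape}, \code{mean}, \code{leftVariance},
#'   \code{rightVariance}.
#' @export
fitAGGD <- function(samples) {
  samples <- samples[is.finite(samples)]
  stopifnot(length(samples) >= 100L)
  neg <- samples[samples < 0]; pos <- samples[samples > 0]
  if (!length(neg) || !length(pos)) stop("degenerate fit: one-sided samples")
  lsq <- sqrt(mean(neg^2)); rsq <- sqrt(mean(pos^2))
  gam <- lsq / rsq
  rhat <- mean(abs(samples))^2 / mean(samples^2)
  Rhat <- rhat * (gam^3 + 1) * (gam + 1) / (gam^2 + 1)^2
  shape <- invertMomentRatio(1 / Rhat)
  eta <- (rsq - lsq) * exp(lgamma(2 / shape) - lgamma(1 / shape)) *
    sqrt(exp(lgamma(1 / shape) - lgamma(3 / shape)))
  list(shape = shape, mean = eta, leftVariance = lsq^2,
       rightVariance = rsq^2)
}

#' BRISQUE 36-dimensional feature vector
#'
#' 18 features per scale at two scales (native and 2x mean-pooled): GGD
#' (shape, variance) of the MSCN coefficients plus AGGD (shape, mean,
#' left variance, right variance) of the four directional pairwise
#' products.
#'
#' @param img a \linkS4class{PAImage} of at least 32 x 32.
#' @return named numeric vector of length 36.
#' @export
brisqueFeatures <- function(img) {
  m <- pixels(img)
  stopifnot(nrow(m) >= 32L, ncol(m) >= 32L)
  feats <- c(scaleFeatures(img, 1L),
             scaleFeatures(PAImage(meanPool2(m), dataRange(img),
                                   imageId(img)), 2L))
  stopifnot(length(feats) == 36L)
  feats
}

scaleFeatures <- function(img, scaleIdx) {
  f <- mscn(img)
  co <- f$coefficients
  g <- fitGGD(as.vector(co))
  out <- c(g$shape, g$variance)
  names(out) <- paste0("s", scaleIdx, "_mscn_", c("shape", "var"))
  pp <- pairwiseProducts(co)
  for (d in names(pp)) {
    a <- fitAGGD(as.vector(pp[[d]]))
    v <- c(a$shape, a$mean, a$leftVariance, a$rightVariance)
    names(v) <- paste0("s", scaleIdx, "_", tolower(d), "_",
                       c("shape", "mean", "lvar", "rvar"))
    out <- c(out, v)
  }
  out
}

#' Write BRISQUE features for a set of images as CSV
#'
#' @param images list of \linkS4class{PAImage} objects.
#' @param path output CSV path.
#' @return the feature matrix, invisibly.
#' @export
writeBrisqueCSV <- function(images, path) {
  rows <- t(vapply(images, brisqueFeatures, numeric(36)))
  df <- data.frame(image_id = vapply(images, imageId, character(1)), rows,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
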