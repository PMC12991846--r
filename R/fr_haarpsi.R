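# Haar wavelet perceptual similarity index (Reisenhofer et al. style):
# similarity of first- and second-level Haar coefficient magnitudes,
# weighted by third-level magnitudes, squashed through a logistic map.

haarFilter <- function(level) {
  n <- 2^level
  f <- matrix(1 / n, n, n)
  f[seq_len(n / 2), ] <- -f[seq_len(n / 2), ]
  f # horizontal-edge filter; transpose gives the vertical one
}

haarDecompose <- function(m, levels) {
  lapply(seq_len(levels), function(j) {
    f <- haarFilter(j)
    list(h = filt2(m, f, "same", "symmetric"),
         v = filt2(m, t(f), "same", "symmetric"))
  })
}

#' Haar wavelet perceptual similarity (HaarPSI)
#'
#' Both images are (optionally) 2x2 mean-pooled, decomposed with Haar
#' high-pass filters at three dyadic levels in the horizontal and
#' vertical directions. Local similarities of the magnitudes of the two
#' finest levels, \code{(2ab + C)/(a^2 + b^2 + C)} averaged over levels,
#' are passed through a logistic \code{1/(1+exp(-alpha s))}, averaged
#' with weights \code{max(|c3_x|, |c3_y|)} from the coarsest level, and
#' the weighted mean is mapped back through the squared inverse logistic.
#' \code{C} is defined on the 0-255 scale and rescaled by
#' \code{(R/255)^2}.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param cfg \code{\link{haarpsiConfig}}.
#' @return a \linkS4class{MetricResult} in [0, 1]; higher is better.
#' @export
haarpsi <- function(pair, cfg = haarpsiConfig()) {
  p <- pairMatrices(pair)
  x <- p$x; y <- p$y
  if (cfg$subsample) { x <- meanPool2(x); y <- meanPool2(y) }
  C <- cfg$C * p$R^2
  a <- cfg$alpha
  dx <- haarDecompose(x, cfg$levels)
  dy <- haarDecompose(y, cfg$levels)
  num <- 0; den <- 0
  for (dir in c("h", "v")) {
    s <- 0
    for (j in 1:2) {
      cx <- abs(dx[[j]][[dir]]); cy <- abs(dy[[j]][[dir]])
      s <- s + (2 * cx * cy + C) / (cx^2 + cy^2 + C)
    }
    s <- s / 2
    w <- pmax(abs(dx[[cfg$levels]][[dir]]), abs(dy[[cfg$levels]][[dir]]))
    num <- num + sum(w / (1 + exp(-a * s)))
    den <- den + sum(w)
  }
  if (den == 0) { # two blank images: similarity is perfect by convention
    return(metricResult("HAARPSI", 1.0, TRUE))
  }
  q <- num / den
  v <- (log(q / (1 - q)) / a)^2
  metricResult("HAARPSI", min(max(v, 0), 1), TRUE)
}
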