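# Internal filtering primitives shared by the metric implementations.

# normalized 2-D Gaussian kernel
gaussianKernel <- function(size, sigma) {
  r <- (size - 1) / 2
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# cross-correlation filter; mode "valid"/"same"; boundary "zero"/"symmetric"
filt2 <- function(A, K, mode = "valid", boundary = "zero") {
  .cc_filter2(A, K, mode, boundary)
}

meanPool2 <- function(A) .cc_meanpool2(A)

resizeBilinear <- function(A, h, w) .cc_resize_bilinear(A, h, w)

# Gaussian-window local moments of a pair, valid region
localMoments <- function(x, y, K) {
  mx <- filt2(x, K); my <- filt2(y, K)
  sxx <- filt2(x * x, K) - mx^2
  syy <- filt2(y * y, K) - my^2
  sxy <- filt2(x * y, K) - mx * my
  list(mx = mx, my = my, sxx = pmax(sxx, 0), syy = pmax(syy, 0), sxy = sxy)
}

# sigma rule for an adaptive-threshold Gaussian window of odd size n
adaptiveSigma <- function(n) 0.3 * ((n - 1) / 2 - 1) + 0.8
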