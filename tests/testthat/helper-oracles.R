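# Independent literal recomputations of the metric formulas in plain R,
# written against the published definitions (offset-shift accumulation,
# no shared filtering code with the package internals). These serve as
# oracles for the fast implementation paths.

oGauss <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid cross-correlation by explicit offset accumulation
oFilterValid <- function(A, K) {
  kh <- nrow(K); kw <- ncol(K)
  oh <- nrow(A) - kh + 1L; ow <- ncol(A) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    out <- out + K[i, j] * A[i:(i + oh - 1L), j:(j + ow - 1L)]
  }
  out
}

oPadSym <- function(A, p) {
  n <- nrow(A); m <- ncol(A)
  ri <- c(p:1, 1:n, n:(n - p + 1L))
  ci <- c(p:1, 1:m, m:(m - p + 1L))
  A[ri, ci]
}

oFilterSameSym <- function(A, K) {
  p <- (nrow(K) - 1L) / 2L
  oFilterValid(oPadSym(A, p), K)
}

oSSIMcomp <- function(x, y, R, K1 = 0.01, K2 = 0.03, win = 11L,
                      sigma = 1.5) {
  K <- oGauss(win, sigma)
  C1 <- (K1 * R)^2; C2 <- (K2 * R)^2
  mx <- oFilterValid(x, K); my <- oFilterValid(y, K)
  sxx <- pmax(oFilterValid(x * x, K) - mx^2, 0)
  syy <- pmax(oFilterValid(y * y, K) - my^2, 0)
  sxy <- oFilterValid(x * y, K) - mx * my
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(map = l * cs, l = l, cs = cs)
}

oSSIM <- function(x, y, R = 1) mean(oSSIMcomp(x, y, R)$map)

oMeanPool <- function(A) {
  H <- nrow(A) %/% 2L; W <- ncol(A) %/% 2L
  0.25 * (A[2 * seq_len(H) - 1L, 2 * seq_len(W) - 1L, drop = FALSE] +
          A[2 * seq_len(H),      2 * seq_len(W) - 1L, drop = FALSE] +
          A[2 * seq_len(H) - 1L, 2 * seq_len(W),      drop = FALSE] +
          A[2 * seq_len(H),      2 * seq_len(W),      drop = FALSE])
}

oMSSSIM <- function(x, y, R = 1, M = 5L,
                    w = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  if (M != length(w)) w <- w[seq_len(M)] / sum(w[seq_len(M)])
  if (M == 1L) w <- 1
  val <- 1
  for (j in seq_len(M)) {
    s <- oSSIMcomp(x, y, R)
    term <- if (j < M) mean(s$cs) else mean(s$map)
    val <- val * max(term, 0)^w[j]
    if (j < M) { x <- oMeanPool(x); y <- oMeanPool(y) }
  }
  val
}

oGMSDmap <- function(x, y, R, c0 = 170 / 255^2) {
  x <- oMeanPool(x); y <- oMeanPool(y)
  px <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3, 3)
  gm <- function(m) sqrt(oFilterSameSym(m, px)^2 + oFilterSameSym(m, t(px))^2)
  gx <- gm(x); gy <- gm(y)
  cc <- c0 * R^2
  (2 * gx * gy + cc) / (gx^2 + gy^2 + cc)
}

oGMSD <- function(x, y, R = 1) {
  s <- oGMSDmap(x, y, R)
  sqrt(mean((s - mean(s))^2))
}

oMSGMSD <- function(x, y, R = 1, scales = 4L) {
  vals <- numeric(scales)
  for (j in seq_len(scales)) {
    vals[j] <- oGMSD(x, y, R)
    if (j < scales) { x <- oMeanPool(x); y <- oMeanPool(y) }
  }
  sqrt(mean(vals^2))
}

oUQI <- function(x, y, ws = 8L, eps = 1e-12) {
  K <- matrix(1 / ws^2, ws, ws)
  mx <- oFilterValid(x, K); my <- oFilterValid(y, K)
  sxx <- pmax(oFilterValid(x * x, K) - mx^2, 0)
  syy <- pmax(oFilterValid(y * y, K) - my^2, 0)
  sxy <- oFilterValid(x * y, K) - mx * my
  mean(4 * mx * my * sxy / ((mx^2 + my^2 + eps) * (sxx + syy + eps)))
}

oVIF <- function(x, y, R = 1, sn2_255 = 2, ws = 9L) {
  K <- matrix(1 / ws^2, ws, ws)
  mx <- oFilterValid(x, K); my <- oFilterValid(y, K)
  sxx <- pmax(oFilterValid(x * x, K) - mx^2, 0)
  sxy <- oFilterValid(x * y, K) - mx * my
  g <- sxy / (sxx + 1e-10)
  g[g < 0] <- 0
  sn2 <- sn2_255 * (R / 255)^2
  info <- log(1 + sxx / sn2)
  sum(g * info) / sum(info)
}
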