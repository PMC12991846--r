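# Shared fixtures: deterministic random image pairs and small phantoms.

randomPair <- function(seed, n = 64L, noiseSd = 0.08) {
  set.seed(seed)
  x <- matrix(runif(n * n), n)
  y <- pmin(pmax(x + rnorm(n * n, sd = noiseSd), 0), 1)
  validatePair(PAImage(x, id = "ref"), PAImage(y, id = "test"))
}

vesselPair <- function(seed = 3L, noiseSd = 0.05) {
  ph <- generatePhantom("vessel", seed = seed)
  set.seed(seed + 1L)
  noisy <- PAImage(pmin(pmax(pixels(ph) +
                               rnorm(length(pixels(ph)), sd = noiseSd),
                             0), 1), id = "noisy")
  validatePair(ph, noisy)
}

tmpDir <- function() {
  d <- tempfile("paiq")
  dir.create(d)
  d
}
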