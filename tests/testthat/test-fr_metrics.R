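test_that("PSNR matches its closed form and reports Inf on identity", {
  set.seed(10)
  x <- matrix(runif(64 * 64), 64)
  p <- validatePair(PAImage(x), PAImage(x))
  expect_identical(metricValue(psnr(p)), Inf)
  # uniform offset of 0.5 everywhere: MSE 0.25 -> 6.0206 dB
  a <- PAImage(matrix(0, 16, 16)); b <- PAImage(matrix(0.5, 16, 16))
  expect_equal(metricValue(psnr(validatePair(a, b))), 10 * log10(1 / 0.25),
               tolerance = 1e-9)
  expect_equal(metricValue(psnr(validatePair(a, b))), 6.0206, tolerance = 1e-4)
  # checkerboard perturbation of amplitude 0.1: MSE 0.01 -> 20 dB
  cb <- 0.1 * outer(1:16, 1:16, function(i, j) (-1)^(i + j))
  d <- PAImage(matrix(0.5, 16, 16) + cb)
  expect_equal(metricValue(psnr(validatePair(b, d))), 20.0, tolerance = 1e-9)
})

test_that("SSIM identity, constant-image closed form, and oracle agreement", {
  p <- randomPair(1)
  expect_equal(metricValue(ssim(validatePair(p@reference, p@reference))), 1.0)
  # constant 1 vs constant 0 with R = 1: (C1 C2)/((1+C1) C2)
  c1 <- PAImage(matrix(1, 16, 16)); c0 <- PAImage(matrix(0, 16, 16))
  expect_equal(metricValue(ssim(validatePair(c1, c0))), 1e-4 / 1.0001,
               tolerance = 1e-12)
  # windowed brute-force oracle on random pairs
  for (s in 1:4) {
    pr <- randomPair(s)
    expect_equal(metricValue(ssim(pr)),
                 oSSIM(pixels(pr@reference), pixels(pr@test)),
                 tolerance = 1e-6)
  }
  expect_error(ssim(randomPair(1, n = 8L)), "window")
})

test_that("SSIM agrees with an external reference implementation value", {
  # frozen scikit-image structural_similarity (gaussian_weights, sigma 1.5,
  # population covariance, data_range 1) on this exact fixture
  pr <- randomPair(42)
  expect_equal(metricValue(ssim(pr)), 0.9637422391643, tolerance = 1e-9)
})

test_that("MS-SSIM reduces to SSIM at one scale and matches the product formula", {
  pr <- randomPair(5, n = 128L)
  expect_equal(metricValue(msSSIM(validatePair(pr@reference, pr@reference),
                                  msssimConfig(scales = 4L))), 1.0)
  expect_equal(metricValue(msSSIM(pr, msssimConfig(scales = 1L))),
               metricValue(ssim(pr)), tolerance = 1e-9)
  for (s in 1:3) {
    pr <- randomPair(s + 100, n = 128L)
    got <- suppressWarnings(metricValue(msSSIM(pr)))
    want <- oMSSSIM(pixels(pr@reference), pixels(pr@test), M = 4L)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("GMSD hits identity, constructed-map std, and literal recomputation", {
  pr <- randomPair(6)
  expect_equal(metricValue(gmsd(validatePair(pr@reference, pr@reference))), 0)
  # similarity map {1, 0.5} on equal halves has std 0.25
  m <- c(rep(1, 50), rep(0.5, 50))
  expect_equal(sqrt(mean((m - mean(m))^2)), 0.25)
  for (s in 1:4) {
    pr <- randomPair(s + 20)
    expect_equal(metricValue(gmsd(pr)),
                 oGMSD(pixels(pr@reference), pixels(pr@test)),
                 tolerance = 1e-9)
  }
})

test_that("MS-GMSD reduces to GMSD at one scale and matches its multi-scale oracle", {
  pr <- randomPair(7, n = 128L)
  expect_equal(metricValue(msGMSD(validatePair(pr@reference, pr@reference))), 0)
  expect_equal(metricValue(msGMSD(pr, gmsdConfig(scales = 1L))),
               metricValue(gmsd(pr)), tolerance = 1e-12)
  for (s in 1:3) {
    pr <- randomPair(s + 30, n = 128L)
    expect_equal(metricValue(msGMSD(pr)),
                 oMSGMSD(pixels(pr@reference), pixels(pr@test)),
                 tolerance = 1e-9)
  }
})

test_that("pixel-domain VIF: identity, degradation direction, oracle, degenerate input", {
  pr <- randomPair(8)
  expect_equal(metricValue(vifP(validatePair(pr@reference, pr@reference))),
               1.0, tolerance = 1e-8)
  set.seed(9)
  x <- matrix(runif(64 * 64), 64)
  y <- pmin(pmax(x + rnorm(64 * 64, sd = 0.3), 0), 1)
  expect_lt(metricValue(vifP(validatePair(PAImage(x), PAImage(y)))), 1)
  for (s in 1:4) {
    pr <- randomPair(s + 40)
    expect_equal(metricValue(vifP(pr)),
                 oVIF(pixels(pr@reference), pixels(pr@test)),
                 tolerance = 1e-6)
  }
  flat <- PAImage(matrix(0.5, 32, 32))
  expect_error(vifP(validatePair(flat, flat)), "constant")
})

test_that("UQI: identity, anticorrelation sign, and sliding-window oracle", {
  pr <- randomPair(10)
  expect_equal(metricValue(uqi(validatePair(pr@reference, pr@reference))),
               1.0, tolerance = 1e-6)
  # negated image: covariance negative in every window
  set.seed(11)
  x <- matrix(runif(64 * 64, 0.2, 0.8), 64)
  y <- 1 - x
  expect_lt(metricValue(uqi(validatePair(PAImage(x), PAImage(y)))), 0)
  for (s in 1:4) {
    pr <- randomPair(s + 50)
    expect_equal(metricValue(uqi(pr)),
                 oUQI(pixels(pr@reference), pixels(pr@test)),
                 tolerance = 1e-9)
  }
})

test_that("HaarPSI: identity, range bound, and subsampling toggle", {
  pr <- randomPair(12)
  expect_equal(metricValue(haarpsi(validatePair(pr@reference,
                                                pr@reference))), 1.0)
  for (s in 1:20) {
    set.seed(s + 300)
    a <- PAImage(matrix(runif(32 * 32), 32))
    b <- PAImage(matrix(runif(32 * 32), 32))
    v <- metricValue(haarpsi(validatePair(a, b)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  v1 <- metricValue(haarpsi(pr, haarpsiConfig(subsample = FALSE)))
  expect_gte(v1, 0); expect_lte(v1, 1)
})

test_that("FSIM: identity, exponent degeneracy, and range", {
  pr <- vesselPair(4)
  expect_equal(metricValue(fsim(validatePair(pr@reference, pr@reference))),
               1.0)
  # alpha = 0: score depends only on gradient similarity
  r <- fsim(pr, fsimConfig(alpha = 0))
  d <- r@details
  expect_equal(metricValue(r), sum(d$sG * d$pcMax) / sum(d$pcMax),
               tolerance = 1e-9)
  for (s in 1:5) {
    p2 <- randomPair(s + 70)
    v <- metricValue(fsim(p2))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("IW-SSIM: identity, uniform-weight degeneracy to MS-SSIM, and range", {
  pr <- randomPair(13, n = 128L)
  expect_equal(suppressWarnings(
    metricValue(iwSSIM(validatePair(pr@reference, pr@reference)))), 1.0)
  expect_equal(suppressWarnings(metricValue(iwSSIM(pr, uniformWeights = TRUE))),
               suppressWarnings(metricValue(msSSIM(pr))), tolerance = 1e-6)
  for (s in 1:5) {
    p2 <- randomPair(s + 80, n = 128L)
    v <- suppressWarnings(metricValue(iwSSIM(p2)))
    expect_gte(v, 0); expect_lte(v, 1 + 1e-9)
  }
})

test_that("structure masks: neighborhood rule, constant image, bright line", {
  expect_equal(paiq:::s3imNeighborhood(128), 17L)
  expect_equal(paiq:::s3imNeighborhood(64), 9L)
  # constant image has no structure
  expect_false(any(s3imMask(PAImage(matrix(0.4, 64, 64)))))
  # a bright 3-px line is masked with at most a neighborhood-wide halo
  m <- matrix(0, 128, 128); m[63:65, ] <- 1
  mask <- s3imMask(PAImage(m))
  expect_true(all(mask[63:65, 10:118]))
  expect_lt(mean(mask), 0.20)
})

test_that("S3IM: identity, all-ones mask reduction, masked-mean oracle, empty mask", {
  pr <- vesselPair(5)
  expect_equal(metricValue(s3im(validatePair(pr@reference, pr@reference))),
               1.0)
  ones <- matrix(TRUE, 128, 128)
  expect_equal(metricValue(s3im(pr, mask = ones)), metricValue(ssim(pr)),
               tolerance = 1e-9)
  # literal recomputation of sum(map*mask)/sum(mask)
  mask <- s3imMask(pr@reference) | s3imMask(pr@test)
  xm <- pixels(pr@reference) * mask; ym <- pixels(pr@test) * mask
  map <- oSSIMcomp(xm, ym, 1)$map
  mv <- mask[6:123, 6:123]
  expect_equal(metricValue(s3im(pr)), sum(map * mv) / sum(mv),
               tolerance = 1e-9)
  blank <- validatePair(PAImage(matrix(0, 64, 64)),
                        PAImage(matrix(0, 64, 64)))
  expect_warning(r <- s3im(blank), "empty|structureless")
  expect_equal(metricValue(r), 1.0)
})

test_that("the dispatcher returns all metrics in order with direction flags", {
  pr <- randomPair(14)
  df <- suppressWarnings(computeAllFR(pr))
  expect_equal(df$metric, frMetrics())
  expect_equal(nrow(df), 11L)
  expect_true(all(is.finite(df$value)))
  expect_equal(df$higher_is_better[df$metric %in% c("GMSD", "MS-GMSD")],
               c(FALSE, FALSE))
  # identity pattern by direction
  idp <- validatePair(pr@reference, pr@reference)
  dfi <- suppressWarnings(computeAllFR(idp))
  hb <- dfi$higher_is_better
  expect_true(all(dfi$value[hb] >= 1 - 1e-6))
  expect_true(all(dfi$value[!hb] == 0))
  # symmetric metrics are invariant under argument swap
  rev <- validatePair(pr@test, pr@reference)
  for (m in c("PSNR", "SSIM", "GMSD", "MS-GMSD", "UQI")) {
    a <- suppressWarnings(computeAllFR(pr, metrics = m))$value
    b <- suppressWarnings(computeAllFR(rev, metrics = m))$value
    expect_equal(a, b, tolerance = 1e-9, label = m)
  }
  expect_error(computeAllFR(pr, metrics = "NOPE"), "unknown")
})

test_that("added noise degrades every metric monotonically on average", {
  ph <- generatePhantom("vessel", seed = 21)
  sigmas <- c(0.02, 0.05, 0.1, 0.2)
  reps <- 8L
  means <- matrix(0, length(sigmas), 11L)
  for (si in seq_along(sigmas)) {
    acc <- 0
    for (r in seq_len(reps)) {
      set.seed(1000 * si + r)
      noisy <- PAImage(pmin(pmax(pixels(ph) +
        rnorm(128 * 128, sd = sigmas[si]), 0), 1))
      df <- suppressWarnings(computeAllFR(validatePair(ph, noisy)))
      acc <- acc + df$value
    }
    means[si, ] <- acc / reps
  }
  dirs <- suppressWarnings(
    computeAllFR(randomPair(1)))$higher_is_better
  for (k in seq_len(11L)) {
    if (dirs[k]) expect_true(all(diff(means[, k]) < 0),
                             label = paste(frMetrics()[k], "decreasing"))
    else expect_true(all(diff(means[, k]) > 0),
                     label = paste(frMetrics()[k], "increasing"))
  }
})
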