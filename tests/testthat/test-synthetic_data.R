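# 4-neighborhood connected component count for the phantom layout checks
componentCount <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cc <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cc <- cc + 1L
    stack <- s
    lab[s] <- cc
    n <- nrow(mask)
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (p - 1L) %% n + 1L; j <- (p - 1L) %/% n + 1L
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= n && jj >= 1L && jj <= ncol(mask)) {
          q <- (jj - 1L) * n + ii
          if (mask[q] && lab[q] == 0L) { lab[q] <- cc; stack <- c(stack, q) }
        }
      }
    }
  }
  cc
}

test_that("phantoms are reproducible and within foreground bounds", {
  a <- generatePhantom("vessel", seed = 7)
  b <- generatePhantom("vessel", seed = 7)
  expect_identical(pixels(a), pixels(b))
  for (s in c(1, 9, 23)) {
    fg <- mean(pixels(generatePhantom("vessel", seed = s)) > 0.1)
    expect_gte(fg, 0.02); expect_lte(fg, 0.25)
  }
  # distinct seeds give distinct phantoms
  expect_false(identical(pixels(a),
                         pixels(generatePhantom("vessel", seed = 8))))
})

test_that("Derenzo phantoms have exactly the specified disc count", {
  for (s in c(3, 11)) {
    dz <- generatePhantom("derenzo", seed = s)
    expect_equal(componentCount(pixels(dz) > 0.1), 6L * 3L)
  }
  dz2 <- generatePhantom("derenzo", nSectors = 4L, discsPerSector = 3L,
                         seed = 2)
  expect_equal(componentCount(pixels(dz2) > 0.1), 12L)
})

test_that("sparse-view degradation is deterministic and orders with angle count", {
  ph <- generatePhantom("vessel", seed = 5)
  d1 <- degradeSparseView(ph, 32)
  d2 <- degradeSparseView(ph, 32)
  expect_identical(pixels(d1), pixels(d2))
  # near-complete reconstruction at dense sampling
  full <- degradeSparseView(ph, 720)
  expect_gt(metricValue(ssim(validatePair(ph, full))), 0.9)
  s8 <- metricValue(ssim(validatePair(ph, degradeSparseView(ph, 8))))
  s128 <- metricValue(ssim(validatePair(ph, degradeSparseView(ph, 128))))
  expect_lt(s8, s128)
})

test_that("frame averaging noise follows sigma0/sqrt(n) and vanishes in the limit", {
  flat <- PAImage(matrix(0.5, 64, 64))
  d <- degradeFrameAveraging(flat, 4L, sigma0 = 0.2, seed = 9)
  expect_equal(sd(pixels(d) - 0.5), 0.1, tolerance = 0.05)
  ph <- generatePhantom("vessel", seed = 2)
  lim <- degradeFrameAveraging(ph, 1e6, sigma0 = 2, seed = 9)
  expect_lt(sqrt(mean((pixels(lim) - pixels(ph))^2)), 1e-2)
  expect_identical(pixels(degradeFrameAveraging(ph, 64L, 2, seed = 3)),
                   pixels(degradeFrameAveraging(ph, 64L, 2, seed = 3)))
})

test_that("SNR-in-dB degradation hits its target noise level", {
  ph <- generatePhantom("vessel", seed = 3)
  d <- degradeSNR(ph, 20, seed = 5)
  res <- pixels(d) - pixels(ph)
  target <- sqrt(mean(pixels(ph)^2)) / 10
  expect_equal(sd(res[pixels(ph) > 0.2 & pixels(ph) < 0.8]), target,
               tolerance = 0.1)
})

test_that("ladders write valid manifests with per-image references", {
  d <- tmpDir()
  man <- buildLadder(d, "demo", "vessel", "sparse_view",
                     levels = c(8L, 32L, 128L), nImages = 3L, seed = 2)
  st <- subsetTable(man)
  expect_equal(nrow(st), 3L)
  expect_equal(st$n, rep(3L, 3))
  expect_equal(st$quality_rank, 1:3)
  rec <- man@records
  # each test image pairs with its own clean reference
  expect_equal(sub(".*_(\\d+)\\.tif", "\\1", basename(rec$path_test)),
               sub(".*_(\\d+)\\.tif", "\\1", basename(rec$path_reference)))
  expect_true(all(file.exists(rec$path_test)))
  expect_true(all(file.exists(rec$path_reference)))
  # mean SSIM per subset strictly increases with quality rank
  sc <- scoreManifest(man, metrics = "SSIM")
  mu <- tapply(sc$value, sc$quality_rank, mean)
  expect_true(all(diff(mu) > 0))
})

test_that("the benchmark suite is reproducible and domain shift changes statistics", {
  d1 <- tmpDir(); d2 <- tmpDir()
  s1 <- buildBenchmarkSuite(d1, seed = 4, nImages = 2L)
  s2 <- buildBenchmarkSuite(d2, seed = 4, nImages = 2L)
  expect_length(s1, 4L)
  expect_named(s1, c("vessel_sparse", "vessel_frames", "derenzo_sparse",
                     "shifted_derenzo"))
  f1 <- s1$vessel_sparse@records$path_test[1]
  f2 <- s2$vessel_sparse@records$path_test[1]
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # local contrast of the shifted ladder differs by > 20%
  localContrast <- function(man) {
    mean(vapply(man@records$path_test[1:4], function(p) {
      m <- pixels(normalizeMinmax(loadImage(p)))
      mu <- paiq:::filt2(m, matrix(1 / 49, 7, 7), "same", "symmetric")
      s2 <- paiq:::filt2(m^2, matrix(1 / 49, 7, 7), "same", "symmetric")
      mean(sqrt(pmax(s2 - mu^2, 0)))
    }, numeric(1)))
  }
  cin <- localContrast(s1$derenzo_sparse)
  csh <- localContrast(s1$shifted_derenzo)
  expect_gt(abs(csh - cin) / cin, 0.2)
})
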