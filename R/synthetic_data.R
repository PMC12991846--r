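# Synthetic photoacoustic-like fixtures: vessel and Derenzo phantoms plus
# the two degradation families seen on real ladders — angular
# undersampling (streak artefacts via Radon projection and filtered
# backprojection) and frame-averaging noise (sd ~ 1/sqrt(n_frames)) —
# and an SNR-in-dB ladder. A domain-shifted configuration (speckle +
# blur) supports out-of-distribution tests.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic phantom image
#'
#' \code{kind = "vessel"}: smooth random-walk branching curves of width
#' 1-4 px on a zero background, emulating vascular networks; foreground
#' occupies roughly 2-25\% of the frame. \code{kind = "derenzo"}: a
#' resolution test pattern of disc triplets arranged in angular sectors
#' with per-sector decreasing radius; discs are disjoint so the
#' connected-component count equals the disc count. Identical
#' specifications reproduce bit-identical phantoms.
#'
#' @param kind \code{"vessel"} or \code{"derenzo"}.
#' @param size image side in pixels (square).
#' @param nBranches number of vessel branches; \code{NULL} (default)
#'   draws 3-7 per phantom so generated cohorts vary in vessel density.
#' @param nSectors,discsPerSector Derenzo layout; each phantom gets a
#'   random pattern rotation and mild radius jitter so cohorts are
#'   distinct.
#' @param intensity peak foreground intensity in (0, 1].
#' @param seed integer seed.
#' @return a \linkS4class{PAImage}.
#' @export
generatePhantom <- function(kind = c("vessel", "derenzo"), size = 128L,
                            nBranches = NULL, nSectors = 6L,
                            discsPerSector = 3L, intensity = 1.0,
                            seed = 1L) {
  kind <- match.arg(kind)
  withSeed(seed, {
    K <- gaussianKernel(3L, 0.7) # mild anti-aliasing
    finish <- function(m) {
      m <- filt2(m, K, "same", "zero")
      if (max(m) > 0) m <- m / max(m) * intensity
      m
    }
    m <- if (kind == "vessel") {
      if (is.null(nBranches)) nBranches <- sample(3:7, 1L)
      v <- finish(vesselPhantom(size, nBranches))
      # redraw sparser networks if the vasculature over-fills the frame
      while (mean(v > 0.1 * intensity) > 0.24 && nBranches > 2L) {
        nBranches <- nBranches - 1L
        v <- finish(vesselPhantom(size, nBranches))
      }
      v
    } else {
      finish(derenzoPhantom(size, nSectors, discsPerSector))
    }
    PAImage(m, dataRange = 1.0,
            id = sprintf("%s_s%d", kind, seed))
  })
}

stampDisc <- function(m, cy, cx, r, value) {
  n <- nrow(m)
  i0 <- max(1, floor(cy - r)); i1 <- min(n, ceiling(cy + r))
  j0 <- max(1, floor(cx - r)); j1 <- min(ncol(m), ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(m)
  for (j in j0:j1) {
    dj2 <- (j - cx)^2
    for (i in i0:i1) {
      if ((i - cy)^2 + dj2 <= r^2 && value > m[i, j]) m[i, j] <- value
    }
  }
  m
}

vesselPhantom <- function(size, nBranches) {
  m <- matrix(0, size, size)
  queue <- list()
  for (b in seq_len(nBranches)) {
    # start just inside a random border, heading inward
    side <- sample(4L, 1L)
    inset <- 3
    pos <- switch(side,
      c(inset, runif(1, 0.2, 0.8) * size),
      c(size - inset, runif(1, 0.2, 0.8) * size),
      c(runif(1, 0.2, 0.8) * size, inset),
      c(runif(1, 0.2, 0.8) * size, size - inset))
    dir <- switch(side, pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, 0.4)
    queue[[length(queue) + 1L]] <-
      list(pos = pos, dir = dir, width = runif(1, 1, 3),
           len = round(runif(1, 0.6, 1.1) * size), depth = 0L)
  }
  amp <- runif(length(queue), 0.6, 1.0)
  bi <- 0L
  while (length(queue) > 0L) {
    br <- queue[[1L]]; queue <- queue[-1L]
    bi <- bi + 1L
    a <- if (bi <= length(amp)) amp[bi] else runif(1, 0.6, 1.0)
    pos <- br$pos; dir <- br$dir; w <- br$width
    for (s in seq_len(br$len)) {
      dir <- dir + rnorm(1, 0, 0.12)
      pos <- pos + c(sin(dir), cos(dir))
      if (any(pos < 1.5) || any(pos > size - 0.5)) break
      w <- min(max(w + rnorm(1, 0, 0.05), 1), 4)
      m <- stampDisc(m, pos[1], pos[2], w / 2, a)
      if (br$depth < 2L && runif(1) < 0.015) { # spawn a side branch
        queue[[length(queue) + 1L]] <-
          list(pos = pos, dir = dir + sample(c(-1, 1), 1) * runif(1, 0.5, 1),
               width = max(w * 0.7, 1), len = round(br$len * 0.5),
               depth = br$depth + 1L)
      }
    }
  }
  m
}

derenzoPhantom <- function(size, nSectors, discsPerSector) {
  m <- matrix(0, size, size)
  c0 <- (size + 1) / 2
  radii <- seq(size / 22, size / 52, length.out = nSectors) *
    runif(1, 0.95, 1.05)
  ringR <- size * runif(1, 0.26, 0.30) # keeps all discs inside the frame
  phase <- runif(1, 0, 2 * pi) # random pattern rotation per phantom
  for (s in seq_len(nSectors)) {
    angle <- phase + 2 * pi * (s - 1) / nSectors
    r <- radii[s]
    gap <- 3.2 * r
    # triangular cluster of discs around the sector center
    offsets <- list(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
    cy <- c0 + ringR * sin(angle); cx <- c0 + ringR * cos(angle)
    for (d in seq_len(discsPerSector)) {
      off <- offsets[[(d - 1L) %% 3L + 1L]] * gap * (1 + (d - 1L) %/% 3L)
      m <- stampDisc(m, cy + off[1], cx + off[2], r, 1.0)
    }
  }
  m
}

#' Sparse-view degradation via Radon projection and filtered backprojection
#'
#' The image is forward-projected over \code{nAngles} equispaced angles
#' in [0, pi), projections are ramp-filtered in the frequency domain and
#' backprojected, and the result is clamped at zero and min-max
#' renormalized. Few angles produce the characteristic streak artefacts
#' of angular undersampling. When a seed is given, measurement noise of
#' sd \code{channelNoise / sqrt(nAngles)} is added to the reconstruction
#' (averaging fewer noisy channels leaves more residual noise); with
#' \code{seed = NULL} the transform is deterministic given
#' (image, nAngles).
#'
#' @param img a \linkS4class{PAImage}.
#' @param nAngles number of view angles (>= 4).
#' @param seed integer seed for the measurement noise, or \code{NULL}
#'   for a noise-free reconstruction.
#' @param channelNoise single-channel noise sd before averaging.
#' @return degraded \linkS4class{PAImage}.
#' @export
degradeSparseView <- function(img, nAngles, seed = NULL,
                              channelNoise = 0.1) {
  stopifnot(nAngles >= 4L)
  m <- pixels(img)
  H <- nrow(m); W <- ncol(m)
  nd <- ceiling(sqrt(2) * max(H, W)) + 2L
  angles <- seq(0, pi, length.out = nAngles + 1L)[seq_len(nAngles)]
  sino <- .cc_radon(m, angles, nd)
  # ramp filter, zero-padded to the next power of two
  nfft <- 2^ceiling(log2(2 * nd))
  f <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / nfft
  ramp <- 2 * f
  filt <- apply(sino, 2L, function(p) {
    P <- stats::fft(c(p, rep(0, nfft - nd)))
    Re(stats::fft(P * ramp, inverse = TRUE) / nfft)[seq_len(nd)]
  })
  rec <- .cc_backproject(filt, angles, H, W)
  rec[rec < 0] <- 0
  if (!is.null(seed)) {
    rec <- withSeed(seed,
      rec + matrix(rnorm(H * W, sd = channelNoise / sqrt(nAngles)), H, W))
    rec[rec < 0] <- 0
  }
  normalizeMinmax(PAImage(rec, dataRange = dataRange(img),
                          id = sprintf("%s_sv%d", imageId(img), nAngles)))
}

#' Frame-averaging noise degradation
#'
#' Adds Gaussian noise of sd \code{sigma0 / sqrt(nFrames)} (the residual
#' noise after averaging \code{nFrames} repeated acquisitions) and clips
#' to [0, 1].
#'
#' @param img a \linkS4class{PAImage} with values in [0, 1].
#' @param nFrames number of averaged frames (>= 1).
#' @param sigma0 single-frame noise sd.
#' @param seed integer seed.
#' @return degraded \linkS4class{PAImage}.
#' @export
degradeFrameAveraging <- function(img, nFrames, sigma0 = 2.0, seed = 1L) {
  stopifnot(nFrames >= 1L, sigma0 > 0)
  withSeed(seed, {
    m <- pixels(img) + rnorm(length(pixels(img)),
                             sd = sigma0 / sqrt(nFrames))
    m <- pmin(pmax(m, 0), 1)
    PAImage(matrix(m, nrow(pixels(img))), dataRange = dataRange(img),
            id = sprintf("%s_f%d", imageId(img), nFrames))
  })
}

#' Additive-noise degradation at a target SNR in dB
#'
#' Noise sd is \code{rms(img) / 10^(snrDb/20)}; output clipped to [0, 1].
#'
#' @param img a \linkS4class{PAImage} with values in [0, 1].
#' @param snrDb target signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @return degraded \linkS4class{PAImage}.
#' @export
degradeSNR <- function(img, snrDb, seed = 1L) {
  withSeed(seed, {
    m <- pixels(img)
    sdn <- sqrt(mean(m^2)) / 10^(snrDb / 20)
    m <- pmin(pmax(m + rnorm(length(m), sd = sdn), 0), 1)
    PAImage(matrix(m, nrow(pixels(img))), dataRange = dataRange(img),
            id = sprintf("%s_snr%g", imageId(img), snrDb))
  })
}

#' Domain-shift transform: speckle plus blur
#'
#' Multiplicative speckle-like noise (sd 0.3) followed by a 2-px Gaussian
#' blur, standing in for an out-of-distribution acquisition chain.
#'
#' @param img a \linkS4class{PAImage}.
#' @param speckleSd multiplicative noise sd.
#' @param blurSigma Gaussian blur sd in pixels.
#' @param seed integer seed.
#' @return shifted \linkS4class{PAImage}.
#' @export
domainShift <- function(img, speckleSd = 0.3, blurSigma = 2, seed = 1L) {
  withSeed(seed, {
    m <- pixels(img)
    m <- m * (1 + rnorm(length(m), sd = speckleSd))
    ks <- 2L * ceiling(2 * blurSigma) + 1L
    m <- filt2(matrix(m, nrow(pixels(img))), gaussianKernel(ks, blurSigma),
               "same", "symmetric")
    normalizeMinmax(PAImage(m, dataRange = dataRange(img),
                            id = paste0(imageId(img), "_shift")))
  })
}

defaultLevels <- function(family) {
  switch(family,
    sparse_view = c(8L, 16L, 32L, 64L, 128L),
    frame_averaging = c(128L, 256L, 384L, 640L, 1280L, 2560L),
    snr_db = c(10L, 20L, 30L, 40L, 50L),
    stop("unknown degradation family: ", family))
}

applyDegradation <- function(img, family, level, sigma0, seed) {
  switch(family,
    sparse_view = degradeSparseView(img, level, seed),
    frame_averaging = degradeFrameAveraging(img, level, sigma0, seed),
    snr_db = degradeSNR(img, level, seed))
}

#' Build a quality ladder on disk
#'
#' Generates \code{nImages} distinct phantoms (per-image seeds
#' \code{seed + index}), stores each clean phantom as the reference, and
#' degrades every phantom at every level of the chosen family; levels are
#' written in increasing order of expected quality with
#' \code{quality_rank} equal to the level index. Images are 16-bit TIFF;
#' the manifest CSV uses the standard header.
#'
#' @param outDir output directory (created).
#' @param dataset dataset name (manifest field and directory label).
#' @param kind phantom kind (\code{\link{generatePhantom}}).
#' @param family \code{"sparse_view"}, \code{"frame_averaging"} or
#'   \code{"snr_db"}.
#' @param levels ordered degradation levels (higher = better quality);
#'   defaults per family (angles 8-128, frames 128-2560, SNR 10-50 dB).
#' @param nImages phantoms per level (>= 2).
#' @param sigma0 single-frame noise sd for frame averaging.
#' @param seed global seed fanned out to per-image seeds.
#' @param shift apply the \code{\link{domainShift}} transform to each
#'   phantom before degradation (domain-shifted ladder).
#' @return the \linkS4class{LadderManifest} (also written to
#'   \code{outDir/manifest.csv}).
#' @export
buildLadder <- function(outDir, dataset, kind = "vessel",
                        family = "sparse_view",
                        levels = defaultLevels(family), nImages = 10L,
                        sigma0 = 2.0, seed = 1L, shift = FALSE) {
  stopifnot(nImages >= 2L, all(diff(levels) > 0))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nImages)) {
    ph <- generatePhantom(kind, seed = seed + i)
    if (shift) ph <- domainShift(ph, seed = seed + 7000L + i)
    refPath <- sprintf("ref_%03d.tif", i)
    writeImage(ph, file.path(outDir, refPath))
    for (li in seq_along(levels)) {
      deg <- applyDegradation(ph, family, levels[li], sigma0,
                              seed = seed + 1000L * li + i)
      sub <- sprintf("%s%d", sub("_.*", "", family), levels[li])
      tPath <- sprintf("%s_%03d.tif", sub, i)
      writeImage(deg, file.path(outDir, tPath))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = dataset, subset = sub, quality_rank = li,
        path_test = tPath, path_reference = refPath,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(outDir, "manifest.csv")
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  readManifest(csv)
}

#' Build the default synthetic benchmark suite
#'
#' Three in-distribution ladders — vessel/sparse-view, vessel/frame-
#' averaging, Derenzo/sparse-view — plus one domain-shifted ladder
#' (Derenzo with speckle and blur, frame-averaging noise) reserved for
#' out-of-distribution evaluation. Regenerates bit-identically from the
#' same seed.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @param nImages phantoms per level in each ladder.
#' @return named list of four \linkS4class{LadderManifest} objects.
#' @export
buildBenchmarkSuite <- function(outDir, seed = 1L, nImages = 10L) {
  list(
    vessel_sparse = buildLadder(file.path(outDir, "vessel_sparse"),
      "vessel_sparse", "vessel", "sparse_view", nImages = nImages,
      seed = seed),
    vessel_frames = buildLadder(file.path(outDir, "vessel_frames"),
      "vessel_frames", "vessel", "frame_averaging", nImages = nImages,
      seed = seed + 100000L),
    derenzo_sparse = buildLadder(file.path(outDir, "derenzo_sparse"),
      "derenzo_sparse", "derenzo", "sparse_view", nImages = nImages,
      seed = seed + 200000L),
    shifted_derenzo = buildLadder(file.path(outDir, "shifted_derenzo"),
      "shifted_derenzo", "derenzo", "frame_averaging", nImages = nImages,
      seed = seed + 300000L, shift = TRUE))
}
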