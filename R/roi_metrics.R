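# Region-based detectability metrics on linear-scale pixel values:
# SNR, CNR, and the histogram-overlap gCNR, averaged over paired
# signal/background ROIs.

#' gCNR histogram configuration
#'
#' @param nBins number of shared histogram bins (default 100) spanning
#'   the joint min-max range of the paired ROIs.
#' @export
gcnrConfig <- function(nBins = 100L) {
  stopifnot(nBins >= 2L)
  list(nBins = as.integer(nBins))
}

roiSd <- function(v) sqrt(mean((v - mean(v))^2)) # population sd

#' Region signal-to-noise ratio
#'
#' \code{mean(signal ROI) / sd(background ROI)} with the population
#' standard deviation.
#'
#' @param img a \linkS4class{PAImage}.
#' @param signal,background \linkS4class{ROI} rectangles inside the image.
#' @return scalar SNR.
#' @export
roiSNR <- function(img, signal, background) {
  s <- cropRegion(img, signal); b <- cropRegion(img, background)
  sb <- roiSd(b)
  if (sb == 0) stop("degenerate ROI: constant background")
  mean(s) / sb
}

#' Region contrast-to-noise ratio
#'
#' \code{|mean(signal) - mean(background)| / sd(background)}.
#'
#' @inheritParams roiSNR
#' @return scalar CNR.
#' @export
roiCNR <- function(img, signal, background) {
  s <- cropRegion(img, signal); b <- cropRegion(img, background)
  sb <- roiSd(b)
  if (sb == 0) stop("degenerate ROI: constant background")
  abs(mean(s) - mean(b)) / sb
}

#' Generalized contrast-to-noise ratio
#'
#' \code{1 - sum_i min(ps(i), pb(i))} where \code{ps}, \code{pb} are the
#' ROI pixel-value histograms normalized to sum 1 over shared bins
#' spanning the joint value range. Equals 1 for disjoint distributions
#' and 0 for identical pixel multisets; invariant under strictly
#' monotonic remapping applied to both ROIs.
#'
#' @inheritParams roiSNR
#' @param cfg \code{\link{gcnrConfig}}.
#' @return scalar in [0, 1].
#' @export
roiGCNR <- function(img, signal, background, cfg = gcnrConfig()) {
  s <- as.vector(cropRegion(img, signal))
  b <- as.vector(cropRegion(img, background))
  gcnrFromSamples(s, b, cfg$nBins)
}

# core histogram-overlap computation on raw sample vectors
gcnrFromSamples <- function(s, b, nBins = 100L) {
  lo <- min(s, b); hi <- max(s, b)
  if (hi == lo) return(0) # all values identical: full overlap
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  hs <- findInterval(s, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  hb <- findInterval(b, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ps <- tabulate(hs, nBins) / length(s)
  pb <- tabulate(hb, nBins) / length(b)
  1 - sum(pmin(ps, pb))
}

#' Per-image detectability report
#'
#' Computes SNR, CNR and gCNR for each signal/background pair of a
#' \linkS4class{ROIPairSet} and averages them into one value per metric,
#' on linear-scale pixel values.
#'
#' @param img a \linkS4class{PAImage}.
#' @param rois a \linkS4class{ROIPairSet}.
#' @param cfg \code{\link{gcnrConfig}}.
#' @return list with \code{snr}, \code{cnr}, \code{gcnr}, \code{nPairs}.
#' @export
detectabilityReport <- function(img, rois, cfg = gcnrConfig()) {
  n <- length(rois@pairs)
  snr <- cnr <- gc <- numeric(n)
  for (i in seq_len(n)) {
    p <- rois@pairs[[i]]
    r <- tryCatch({
      list(snr = roiSNR(img, p$signal, p$background),
           cnr = roiCNR(img, p$signal, p$background),
           gcnr = roiGCNR(img, p$signal, p$background, cfg))
    }, error = function(e) stop("ROI pair ", i, ": ",
                                conditionMessage(e), call. = FALSE))
    snr[i] <- r$snr; cnr[i] <- r$cnr; gc[i] <- r$gcnr
  }
  list(snr = mean(snr), cnr = mean(cnr), gcnr = mean(gc), nPairs = n)
}

#' Read ROI pair sets from CSV
#'
#' Columns: \code{image_id, pair_index, kind, row0, col0, height, width}
#' with \code{kind} in signal/background; one \linkS4class{ROIPairSet}
#' per image id.
#'
#' @param path CSV path.
#' @return named list of \linkS4class{ROIPairSet} objects.
#' @export
readROISets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "pair_index", "kind", "row0", "col0", "height",
            "width")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI file missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$image_id), function(d) {
    pairs <- lapply(sort(unique(d$pair_index)), function(i) {
      di <- d[d$pair_index == i, ]
      getKind <- function(k) {
        r <- di[di$kind == k, ]
        if (nrow(r) != 1L)
          stop("pair ", i, " needs exactly one '", k, "' ROI")
        ROI(r$row0, r$col0, r$height, r$width, kind = k)
      }
      list(signal = getKind("signal"), background = getKind("background"))
    })
    do.call(ROIPairSet, pairs)
  })
  out
}
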