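#' @import methods
#' @importFrom stats fft sd var quantile rnorm runif setNames t.test cor
#'   uniroot cor.test
#' @importFrom utils read.csv write.csv
#' @useDynLib paiq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Single 2-D grayscale photoacoustic image
#'
#' Container for one reconstructed image: a real-valued intensity matrix
#' together with its data range (the maximum possible pixel value, 1.0
#' after min-max normalization) and an identifier.
#'
#' @slot pixels numeric matrix (rows x cols) of intensities.
#' @slot dataRange positive scalar; maximum possible pixel value.
#' @slot id character label.
#' @export
setClass("PAImage",
  representation(pixels = "matrix", dataRange = "numeric", id = "character"),
  prototype(dataRange = 1.0, id = ""))

setValidity("PAImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (nrow(p) < 8L || ncol(p) < 8L) return("image must be at least 8 x 8")
  if (length(object@dataRange) != 1L || !is.finite(object@dataRange) ||
      object@dataRange <= 0) return("dataRange must be a positive scalar")
  TRUE
})

#' Reference/test image pair
#'
#' The unit of full-reference metric computation: a reference image and a
#' test (reconstructed) image of identical shape and data range.
#'
#' @slot reference,test \linkS4class{PAImage} objects.
#' @export
setClass("PAImagePair",
  representation(reference = "PAImage", test = "PAImage"))

setValidity("PAImagePair", function(object) {
  r <- object@reference; t <- object@test
  if (!identical(dim(r@pixels), dim(t@pixels)))
    return(sprintf("shape mismatch between '%s' (%dx%d) and '%s' (%dx%d)",
                   r@id, nrow(r@pixels), ncol(r@pixels),
                   t@id, nrow(t@pixels), ncol(t@pixels)))
  if (!isTRUE(all.equal(r@dataRange, t@dataRange)))
    return(sprintf("data range mismatch between '%s' (%g) and '%s' (%g)",
                   r@id, r@dataRange, t@id, t@dataRange))
  TRUE
})

#' Rectangular region of interest
#'
#' 0-based, row-major, half-open rectangle with top-left origin:
#' rows \code{[row0, row0+height)}, columns \code{[col0, col0+width)}.
#'
#' @slot row0,col0 0-based top-left corner.
#' @slot height,width positive extents.
#' @slot kind \code{"signal"} or \code{"background"}.
#' @export
setClass("ROI",
  representation(row0 = "integer", col0 = "integer",
                 height = "integer", width = "integer", kind = "character"))

setValidity("ROI", function(object) {
  if (object@row0 < 0L || object@col0 < 0L) return("row0/col0 must be >= 0")
  if (object@height < 1L || object@width < 1L)
    return("height/width must be positive")
  if (!object@kind %in% c("signal", "background"))
    return("kind must be 'signal' or 'background'")
  TRUE
})

#' Paired signal/background ROIs
#'
#' A list of (signal, background) ROI pairs; within each pair the two
#' rectangles have identical height and width. Detectability metrics are
#' computed per pair and averaged.
#'
#' @slot pairs list of \code{list(signal = ROI, background = ROI)}.
#' @export
setClass("ROIPairSet", representation(pairs = "list"))

setValidity("ROIPairSet", function(object) {
  if (length(object@pairs) < 1L) return("at least one ROI pair required")
  for (i in seq_along(object@pairs)) {
    p <- object@pairs[[i]]
    if (!is(p$signal, "ROI") || !is(p$background, "ROI"))
      return(sprintf("pair %d must hold 'signal' and 'background' ROIs", i))
    if (p$signal@height != p$background@height ||
        p$signal@width != p$background@width)
      return(sprintf("pair %d: signal and background ROI sizes differ", i))
  }
  TRUE
})

#' Quality-ladder manifest
#'
#' A dataset's subsets ordered by expected quality. Each record maps a
#' test image to its reference image; the integer quality rank increases
#' strictly with expected quality.
#'
#' @slot dataset dataset name.
#' @slot records data.frame with columns \code{subset}, \code{quality_rank},
#'   \code{path_test}, \code{path_reference}, sorted by rank.
#' @export
setClass("LadderManifest",
  representation(dataset = "character", records = "data.frame"))

setValidity("LadderManifest", function(object) {
  rec <- object@records
  need <- c("subset", "quality_rank", "path_test", "path_reference")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  rk <- tapply(rec$quality_rank, rec$subset, unique)
  if (any(lengths(rk) != 1L))
    return("each subset must have a single quality_rank")
  if (anyDuplicated(unlist(rk))) return("quality ranks tie across subsets")
  if (anyDuplicated(rec[, c("subset", "path_test")]))
    return("duplicate (subset, path_test) rows")
  TRUE
})

#' Named scalar metric score
#'
#' @slot metric metric name.
#' @slot value scalar score (may be \code{Inf} for PSNR on identical images).
#' @slot higherIsBetter direction flag.
#' @slot details list of auxiliary outputs (e.g. the per-pixel SSIM map).
#' @export
setClass("MetricResult",
  representation(metric = "character", value = "numeric",
                 higherIsBetter = "logical", details = "list"),
  prototype(details = list()))

setValidity("MetricResult", function(object) {
  if (length(object@value) != 1L) return("value must be scalar")
  if (is.na(object@value)) return("value must not be NA")
  TRUE
})

setMethod("show", "PAImage", function(object) {
  cat(sprintf("PAImage '%s': %d x %d, data range %g, values [%g, %g]\n",
              object@id, nrow(object@pixels), ncol(object@pixels),
              object@dataRange, min(object@pixels), max(object@pixels)))
})

setMethod("show", "PAImagePair", function(object) {
  cat(sprintf("PAImagePair: reference '%s' vs test '%s' (%d x %d)\n",
              object@reference@id, object@test@id,
              nrow(object@reference@pixels), ncol(object@reference@pixels)))
})

setMethod("show", "LadderManifest", function(object) {
  s <- subsetTable(object)
  cat(sprintf("LadderManifest '%s': %d subsets, %d records\n",
              object@dataset, nrow(s), nrow(object@records)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  rank %d: %s (%d images)\n",
                s$quality_rank[i], s$subset[i], s$n[i]))
})

setMethod("show", "MetricResult", function(object) {
  cat(sprintf("%s = %g (%s is better)\n", object@metric, object@value,
              if (object@higherIsBetter) "higher" else "lower"))
})

#' @rdname PAImage-class
#' @param pixels numeric matrix.
#' @param dataRange maximum possible pixel value.
#' @param id image label.
#' @export
PAImage <- function(pixels, dataRange = 1.0, id = "") {
  new("PAImage", pixels = pixels, dataRange = as.numeric(dataRange),
      id = as.character(id))
}

#' @rdname ROI-class
#' @param row0,col0 0-based top-left corner.
#' @param height,width positive extents.
#' @param kind \code{"signal"} or \code{"background"}.
#' @export
ROI <- function(row0, col0, height, width, kind = "signal") {
  new("ROI", row0 = as.integer(row0), col0 = as.integer(col0),
      height = as.integer(height), width = as.integer(width), kind = kind)
}

#' @rdname ROIPairSet-class
#' @param ... \code{list(signal=, background=)} pairs.
#' @export
ROIPairSet <- function(...) new("ROIPairSet", pairs = list(...))

# -- accessors ---------------------------------------------------------------

#' Accessors for paiq classes
#'
#' @param x object.
#' @return \code{pixels}: the intensity matrix; \code{dataRange}: the data
#'   range scalar; \code{imageId}: the label; \code{metricValue}: the scalar
#'   score; \code{subsetTable}: one row per subset with its rank and size.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pixels <- function(x) x@pixels

#' @rdname accessors
#' @export
dataRange <- function(x) x@dataRange

#' @rdname accessors
#' @export
imageId <- function(x) x@id

#' @rdname accessors
#' @export
metricValue <- function(x) x@value

#' @rdname accessors
#' @export
subsetTable <- function(x) {
  rec <- x@records
  s <- unique(rec[, c("subset", "quality_rank")])
  s$n <- as.integer(table(rec$subset)[s$subset])
  s <- s[order(s$quality_rank), , drop = FALSE]
  rownames(s) <- NULL
  s
}
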