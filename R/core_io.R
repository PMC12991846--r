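# Image and manifest I/O, normalization, ROI geometry, pair validation.

#' Load a 2-D grayscale image
#'
#' Reads PNG (8/16-bit), TIFF, or a raw float dump (a binary file of
#' little-endian float32 values with a JSON sidecar \code{<path>.json}
#' holding \code{rows}, \code{cols} and optionally \code{data_range}).
#' Integer formats are scaled by their bit-depth maximum so values land in
#' [0, 1] with data range 1.0; float inputs are kept as-is with the
#' supplied or inferred data range.
#'
#' @param path file path.
#' @param dataRangeHint optional data range for float inputs.
#' @param id image label; defaults to the file name.
#' @return a \linkS4class{PAImage}.
#' @export
loadImage <- function(path, dataRangeHint = NULL, id = basename(path)) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path) # already scaled to [0,1] by bit depth
    m <- squeezeGray(m)
    return(PAImage(m, dataRange = 1.0, id = id))
  }
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    m <- squeezeGray(m)
    return(PAImage(m, dataRange = 1.0, id = id))
  }
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("raw float dump requires a JSON sidecar with rows/cols: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- meta$rows * meta$cols
  v <- readBin(path, what = "numeric", size = 4L, n = n, endian = "little")
  if (length(v) != n) stop("raw dump shorter than rows*cols: ", path)
  m <- matrix(v, nrow = meta$rows, ncol = meta$cols)
  dr <- if (!is.null(dataRangeHint)) dataRangeHint
        else if (!is.null(meta$data_range)) meta$data_range
        else max(m)
  PAImage(m, dataRange = dr, id = id)
}

squeezeGray <- function(m) {
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 1L) m <- m[, , 1L]
    else stop("multi-channel image: expected grayscale")
  }
  if (length(dim(m)) != 2L) stop("image must be 2-D after squeezing")
  m
}

#' Write a grayscale image to disk
#'
#' Values are divided by the image's data range and clipped to [0, 1]
#' before quantization. \code{.tif}/\code{.tiff} paths are written as
#' 16-bit TIFF (the lossless ladder storage format); \code{.png} paths
#' as 8-bit PNG (display/export).
#'
#' @param img a \linkS4class{PAImage}.
#' @param path output path; extension selects the format.
#' @export
writeImage <- function(img, path) {
  m <- pixels(img) / dataRange(img)
  m <- pmin(pmax(m, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path, dpi = NULL)
  } else stop("unsupported output format: .", ext)
  invisible(path)
}

#' @rdname writeImage
#' @export
writeImagePNG <- function(img, path) writeImage(img, path)

#' Min-max normalize an image to [0, 1]
#'
#' Per-image affine rescaling \code{(x - min) / (max - min)} with data
#' range set to 1. A constant image maps to all zeros by convention, so
#' blank frames still flow through batch pipelines.
#'
#' @param img a \linkS4class{PAImage}.
#' @return normalized \linkS4class{PAImage}.
#' @export
normalizeMinmax <- function(img) {
  m <- pixels(img)
  lo <- min(m); hi <- max(m)
  m <- if (hi > lo) (m - lo) / (hi - lo) else array(0, dim(m))
  PAImage(m, dataRange = 1.0, id = imageId(img))
}

#' Crop a rectangular region out of an image
#'
#' Uses the half-open 0-based convention of \linkS4class{ROI}.
#'
#' @param img a \linkS4class{PAImage}.
#' @param roi a \linkS4class{ROI} lying fully inside the image.
#' @return numeric matrix of shape \code{height x width}.
#' @export
cropRegion <- function(img, roi) {
  m <- pixels(img)
  r1 <- roi@row0 + roi@height; c1 <- roi@col0 + roi@width
  if (r1 > nrow(m) || c1 > ncol(m))
    stop(sprintf("ROI [%d,%d)x[%d,%d) outside %d x %d image",
                 roi@row0, r1, roi@col0, c1, nrow(m), ncol(m)))
  m[(roi@row0 + 1L):r1, (roi@col0 + 1L):c1, drop = FALSE]
}

#' Validate and build a reference/test pair
#'
#' Enforces identical shape and data range; the error message names both
#' image ids on mismatch.
#'
#' @param reference,test \linkS4class{PAImage} objects.
#' @return a \linkS4class{PAImagePair}.
#' @export
validatePair <- function(reference, test) {
  new("PAImagePair", reference = reference, test = test)
}

#' Read a quality-ladder manifest from CSV
#'
#' The CSV must have the header
#' \code{dataset,subset,quality_rank,path_test,path_reference}. Records
#' are grouped by subset and subsets sorted by quality rank; ties across
#' distinct subsets and duplicate (subset, path_test) rows are rejected.
#' Relative image paths are resolved against the CSV's directory.
#'
#' @param path CSV path.
#' @return a \linkS4class{LadderManifest}.
#' @export
readManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset", "subset", "quality_rank", "path_test",
            "path_reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$quality_rank) ||
      any(df$quality_rank != round(df$quality_rank)))
    stop("quality_rank must be integer-valued")
  df$quality_rank <- as.integer(df$quality_rank)
  ds <- unique(df$dataset)
  if (length(ds) != 1L) stop("manifest must describe a single dataset")
  base <- dirname(path)
  for (col in c("path_test", "path_reference")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df <- df[order(df$quality_rank, df$path_test), , drop = FALSE]
  rownames(df) <- NULL
  new("LadderManifest", dataset = ds,
      records = df[, c("subset", "quality_rank", "path_test",
                       "path_reference")])
}

#' Write a quality-ladder manifest to CSV
#'
#' @param manifest a \linkS4class{LadderManifest}.
#' @param path output CSV path.
#' @export
writeManifest <- function(manifest, path) {
  df <- cbind(dataset = manifest@dataset, manifest@records)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every (reference, test) pair of a manifest
#'
#' Images are min-max normalized on load (the preprocessing under which
#' all metrics are computed).
#'
#' @param manifest a \linkS4class{LadderManifest}.
#' @param normalize min-max normalize each image (default TRUE).
#' @return list of \code{list(subset, quality_rank, pair)} entries.
#' @export
loadPairs <- function(manifest, normalize = TRUE) {
  rec <- manifest@records
  lapply(seq_len(nrow(rec)), function(i) {
    ref <- loadImage(rec$path_reference[i])
    tst <- loadImage(rec$path_test[i])
    if (normalize) { ref <- normalizeMinmax(ref); tst <- normalizeMinmax(tst) }
    list(subset = rec$subset[i], quality_rank = rec$quality_rank[i],
         pair = validatePair(ref, tst))
  })
}
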