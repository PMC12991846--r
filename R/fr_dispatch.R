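# Uniform dispatcher over the eleven full-reference metrics.

frMetricOrder <- c("PSNR", "SSIM", "MS-SSIM", "IW-SSIM", "S3IM", "HAARPSI",
                   "FSIM", "GMSD", "MS-GMSD", "VIF", "UQI")

#' Names of the eleven full-reference metrics in canonical order
#' @return character vector.
#' @export
frMetrics <- function() frMetricOrder

frDispatch <- function(name, pair, configs) {
  switch(name,
    "PSNR"    = psnr(pair),
    "SSIM"    = ssim(pair, configs$ssim),
    "MS-SSIM" = msSSIM(pair, configs$msssim, configs$ssim),
    "IW-SSIM" = iwSSIM(pair, configs$iwssim, configs$ssim),
    "S3IM"    = s3im(pair, configs$s3im, configs$ssim),
    "HAARPSI" = haarpsi(pair, configs$haarpsi),
    "FSIM"    = fsim(pair, configs$fsim),
    "GMSD"    = gmsd(pair, configs$gmsd),
    "MS-GMSD" = msGMSD(pair, configs$gmsd),
    "VIF"     = vifP(pair, configs$vif),
    "UQI"     = uqi(pair, configs$uqi),
    stop("unknown metric: ", name))
}

#' Default configuration set for all full-reference metrics
#' @return named list of per-metric configs.
#' @export
frConfigs <- function() {
  list(ssim = ssimConfig(), msssim = msssimConfig(), s3im = s3imConfig(),
       gmsd = gmsdConfig(), vif = vifConfig(), uqi = uqiConfig(),
       fsim = fsimConfig(), haarpsi = haarpsiConfig(),
       iwssim = iwssimConfig())
}

#' Compute all eleven full-reference metrics on a pair
#'
#' Metrics are evaluated in a fixed order with their direction flags
#' (GMSD and MS-GMSD are lower-is-better; all others higher-is-better).
#' Per-metric errors are re-raised with the metric name attached.
#'
#' @param pair a \linkS4class{PAImagePair}.
#' @param configs list from \code{\link{frConfigs}}.
#' @param metrics subset of \code{\link{frMetrics}} to compute.
#' @return data.frame with columns \code{metric}, \code{value},
#'   \code{higher_is_better}.
#' @export
computeAllFR <- function(pair, configs = frConfigs(),
                         metrics = frMetrics()) {
  bad <- setdiff(metrics, frMetricOrder)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  metrics <- frMetricOrder[frMetricOrder %in% metrics]
  res <- lapply(metrics, function(nm) {
    r <- tryCatch(frDispatch(nm, pair, configs),
                  error = function(e) stop(nm, ": ", conditionMessage(e),
                                           call. = FALSE))
    data.frame(metric = nm, value = metricValue(r),
               higher_is_better = r@higherIsBetter,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Score every pair of a manifest with full-reference metrics
#'
#' Long-form batch scoring used by the ranking framework; images are
#' min-max normalized before metric computation.
#'
#' @param manifest a \linkS4class{LadderManifest}.
#' @param metrics subset of \code{\link{frMetrics}}.
#' @param configs list from \code{\link{frConfigs}}.
#' @return data.frame with columns \code{dataset}, \code{subset},
#'   \code{quality_rank}, \code{image_id}, \code{metric}, \code{value},
#'   \code{higher_is_better}.
#' @export
scoreManifest <- function(manifest, metrics = frMetrics(),
                          configs = frConfigs()) {
  entries <- loadPairs(manifest)
  rows <- lapply(entries, function(e) {
    df <- computeAllFR(e$pair, configs, metrics)
    cbind(dataset = manifest@dataset, subset = e$subset,
          quality_rank = e$quality_rank,
          image_id = imageId(e$pair@test), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
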