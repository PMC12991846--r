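# Statistical framework ranking metrics by their ability to separate
# known quality levels: pairwise Welch t-tests at p < 0.05, Significant
# Count, Normalized Mean Difference over significant pairs, Composite
# Score CS = SC x NMD, and Spearman correlation against quality rank.

#' Pairwise subset comparisons for one metric
#'
#' One two-sided Welch (unequal-variance) t-test per unordered pair of
#' subsets in a ladder. Subsets with fewer than 2 finite values are
#' skipped with a warning and do not count toward the pair total;
#' non-finite values (e.g. PSNR on identity pairs) are excluded with a
#' message reporting the count.
#'
#' @param scores data.frame with columns \code{subset},
#'   \code{quality_rank}, \code{value} for a single metric (and ladder).
#' @param alpha significance level (0.05).
#' @return data.frame with columns \code{subset_a}, \code{subset_b},
#'   \code{p_value}, \code{mean_diff} (absolute), \code{significant}.
#' @export
pairwiseTests <- function(scores, alpha = 0.05) {
  nInf <- sum(!is.finite(scores$value))
  if (nInf > 0) {
    message(nInf, " non-finite metric value(s) excluded from testing")
    scores <- scores[is.finite(scores$value), , drop = FALSE]
  }
  groups <- split(scores$value, scores$subset)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    warning("subset(s) with < 2 values skipped: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2L]
  }
  labs <- names(groups)
  if (length(labs) < 2L)
    return(data.frame(subset_a = character(), subset_b = character(),
                      p_value = numeric(), mean_diff = numeric(),
                      significant = logical()))
  cmb <- utils::combn(labs, 2L)
  rows <- apply(cmb, 2L, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    p <- tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
      error = function(e) {
        # both samples (essentially) constant: identical means carry no
        # evidence of difference, distinct constant levels separate fully
        if (isTRUE(all.equal(mean(a), mean(b)))) 1.0 else 0.0
      })
    data.frame(subset_a = pr[1], subset_b = pr[2], p_value = p,
               mean_diff = abs(mean(a) - mean(b)),
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significant count
#'
#' Number of subset pairs separated at the significance level.
#'
#' @param comparisons output of \code{\link{pairwiseTests}} (rows from
#'   several ladders may be concatenated).
#' @return integer count.
#' @export
significantCount <- function(comparisons) {
  sum(comparisons$significant)
}

#' Normalized mean difference
#'
#' Mean over the significant comparisons only of
#' \code{|mean_a - mean_b| / value_range}; 0 if no comparison is
#' significant. Absolute differences make lower-is-better metrics rank
#' equivalently.
#'
#' @param comparisons output of \code{\link{pairwiseTests}}.
#' @param valueRange positive metric value range used for normalization.
#' @return scalar NMD >= 0.
#' @export
normalizedMeanDifference <- function(comparisons, valueRange) {
  stopifnot(valueRange > 0)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(0)
  mean(sig$mean_diff / valueRange)
}

#' Composite score CS = SC x NMD
#'
#' @param SC significant count (>= 0).
#' @param NMD normalized mean difference (>= 0).
#' @return scalar composite score.
#' @export
compositeScore <- function(SC, NMD) {
  stopifnot(SC >= 0, NMD >= 0)
  SC * NMD
}

#' Metric value range used for NMD normalization
#'
#' Bounded metrics normalize by their practically attained unit range
#' (SSIM family, UQI, VIF, HaarPSI, FSIM: 1 — matching how the study's
#' worked example normalizes SSIM differences); unbounded metrics use the
#' observed range across the ladder (GMSD family: observed max; PSNR:
#' observed min-max). Overridable.
#'
#' @param metric metric name.
#' @param values observed values for unbounded metrics.
#' @param overrides optional named numeric vector of ranges.
#' @return positive scalar.
#' @export
metricValueRange <- function(metric, values = NULL, overrides = NULL) {
  if (!is.null(overrides) && metric %in% names(overrides))
    return(unname(overrides[metric]))
  bounded <- c("SSIM" = 1, "MS-SSIM" = 1, "IW-SSIM" = 1, "S3IM" = 1,
               "UQI" = 1, "VIF" = 1, "HAARPSI" = 1, "FSIM" = 1)
  if (metric %in% names(bounded)) return(unname(bounded[metric]))
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to derive a range for ", metric)
  if (metric %in% c("GMSD", "MS-GMSD")) return(max(max(abs(v)), 1e-12))
  r <- diff(range(v))
  if (r <= 0) stop("degenerate observed range for ", metric)
  r
}

#' Rank metrics by separability over one or more scored ladders
#'
#' For each metric: Welch tests over all subset pairs within each ladder
#' (dataset), SC summed across ladders, NMD averaged over all significant
#' pairs, CS = SC x NMD. Optional Bonferroni correction divides the
#' significance level by the number of comparisons per metric (off by
#' default, matching a raw p < 0.05 rule).
#'
#' @param scored long-form data.frame from \code{\link{scoreManifest}}
#'   (possibly several ladders concatenated).
#' @param alpha significance level.
#' @param bonferroni apply Bonferroni correction.
#' @param rangeOverrides optional named vector for
#'   \code{\link{metricValueRange}}.
#' @return list with \code{ranking} (metric, SC, NMD, CS, spearman,
#'   n_pairs sorted by descending CS, ties by SC then name) and
#'   \code{detail} (per-pair test rows).
#' @export
rankMetrics <- function(scored, alpha = 0.05, bonferroni = FALSE,
                        rangeOverrides = NULL) {
  stopifnot(nrow(scored) > 0)
  metrics <- unique(scored$metric)
  detail <- list(); rows <- list()
  for (m in metrics) {
    dm <- scored[scored$metric == m, , drop = FALSE]
    cmps <- lapply(split(dm, dm$dataset), function(d) {
      cbind(dataset = d$dataset[1],
            pairwiseTests(d[, c("subset", "quality_rank", "value")],
                          alpha = alpha))
    })
    cmp <- do.call(rbind, cmps)
    rownames(cmp) <- NULL
    if (bonferroni && nrow(cmp)) {
      cmp$significant <- cmp$p_value < alpha / nrow(cmp)
    }
    rng <- metricValueRange(m, dm$value, rangeOverrides)
    SC <- significantCount(cmp)
    NMD <- normalizedMeanDifference(cmp, rng)
    rows[[m]] <- data.frame(metric = m, SC = SC, NMD = NMD,
                            CS = compositeScore(SC, NMD),
                            spearman = spearmanVsQuality(dm),
                            n_pairs = nrow(cmp), stringsAsFactors = FALSE)
    detail[[m]] <- cbind(metric = m, cmp)
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$CS, -ranking$SC, ranking$metric)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  detail <- do.call(rbind, detail)
  rownames(detail) <- NULL
  list(ranking = ranking, detail = detail)
}

#' Spearman correlation between metric values and quality rank
#'
#' Rank correlation of per-image values against their subset's quality
#' rank; constant metric values are undefined and return 0 with a
#' warning.
#'
#' @param scores data.frame with columns \code{value}, \code{quality_rank}
#'   for one metric.
#' @return scalar in [-1, 1].
#' @export
spearmanVsQuality <- function(scores) {
  ok <- is.finite(scores$value)
  v <- scores$value[ok]; q <- scores$quality_rank[ok]
  if (length(unique(v)) < 2L || length(unique(q)) < 2L) {
    warning("constant values: Spearman undefined, returning 0")
    return(0)
  }
  cor(v, q, method = "spearman")
}
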