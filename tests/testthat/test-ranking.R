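mkScores <- function(values, subsets, ranks = seq_along(unique(subsets))) {
  data.frame(subset = subsets,
             quality_rank = ranks[match(subsets, unique(subsets))],
             value = values)
}

test_that("pairwise Welch tests cover all subset pairs and edge cases", {
  # identical lists: p = 1, not significant
  s <- mkScores(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  cmp <- pairwiseTests(s)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
  expect_equal(cmp$mean_diff, 0)
  # strong separation is detected
  set.seed(40)
  s2 <- mkScores(c(rnorm(50, 0), rnorm(50, 5)), rep(c("a", "b"), each = 50))
  cmp2 <- pairwiseTests(s2)
  expect_true(cmp2$significant)
  expect_equal(cmp2$mean_diff, 5, tolerance = 0.5)
  # three subsets give C(3,2) = 3 comparisons
  s3 <- mkScores(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_equal(nrow(pairwiseTests(s3)), 3L)
  # under-filled subsets are skipped with a warning
  s4 <- mkScores(c(rnorm(10), 1), c(rep("a", 5), rep("b", 5), "c"))
  expect_warning(cmp4 <- pairwiseTests(s4), "skipped")
  expect_equal(nrow(cmp4), 1L)
  # non-finite values are excluded with a message
  s5 <- mkScores(c(rnorm(10), Inf), c(rep(c("a", "b"), each = 5), "a"))
  expect_message(pairwiseTests(s5), "non-finite")
})

test_that("significant count, NMD and CS follow their definitions", {
  cmp <- data.frame(significant = c(TRUE, FALSE, TRUE),
                    mean_diff = c(0.2, 9, 0.3), p_value = c(0.01, 0.5, 0.01))
  expect_equal(significantCount(cmp), 2L)
  expect_equal(significantCount(cmp[!cmp$significant, ]), 0L)
  # no significant pairs -> NMD 0
  expect_equal(normalizedMeanDifference(cmp[2, ], 1), 0)
  # one significant pair, |diff| 0.118, range 0.5 -> 0.236
  one <- data.frame(significant = TRUE, mean_diff = 0.118)
  expect_equal(normalizedMeanDifference(one, 0.5), 0.236)
  # mean over significant normalized diffs
  expect_equal(normalizedMeanDifference(cmp, 1), 0.25)
  expect_equal(compositeScore(3L, 0.236), 0.708)
  expect_equal(compositeScore(0L, 0.9), 0)
  expect_equal(compositeScore(10L, 0.1), 1.0)
})

test_that("metric value ranges: unit for bounded metrics, observed otherwise", {
  expect_equal(metricValueRange("SSIM"), 1)
  expect_equal(metricValueRange("UQI"), 1)
  expect_equal(metricValueRange("HAARPSI"), 1)
  expect_equal(metricValueRange("GMSD", c(0.1, 0.02, 0.3)), 0.3)
  expect_equal(metricValueRange("PSNR", c(10, 30, 22)), 20)
  expect_equal(metricValueRange("PSNR", c(10, 30), overrides = c(PSNR = 50)),
               50)
  expect_error(metricValueRange("PSNR", c(Inf, NA)), "no finite")
})

test_that("metric ranking sorts by CS with SC tie-break and loses no rows", {
  set.seed(41)
  mk <- function(metric, gaps) {
    do.call(rbind, lapply(seq_along(gaps), function(i)
      data.frame(dataset = "d", metric = metric,
                 subset = paste0("s", i), quality_rank = i,
                 value = rnorm(10, gaps[i], 0.1))))
  }
  scored <- rbind(mk("SSIM", c(0.2, 0.5, 0.8)),
                  mk("UQI", c(0.4, 0.45, 0.5)),
                  mk("PSNR", c(10, 10.05, 10.1)))
  rk <- rankMetrics(scored)
  expect_setequal(rk$ranking$metric, c("SSIM", "UQI", "PSNR"))
  expect_equal(rk$ranking$CS, sort(rk$ranking$CS, decreasing = TRUE))
  expect_equal(rk$ranking$metric[1], "SSIM")
  expect_equal(rk$ranking$CS, rk$ranking$SC * rk$ranking$NMD)
  expect_true(all(rk$ranking$SC <= rk$ranking$n_pairs))
  # single metric ranks as itself
  rk1 <- rankMetrics(mk("SSIM", c(0.2, 0.8)))
  expect_equal(nrow(rk1$ranking), 1L)
})

test_that("the framework is direction agnostic: negated values keep SC, NMD, CS", {
  set.seed(42)
  mk <- function(metric, sign) {
    do.call(rbind, lapply(1:3, function(i)
      data.frame(dataset = "d", metric = metric, subset = paste0("s", i),
                 quality_rank = i, value = sign * rnorm(12, i * 0.2, 0.08))))
  }
  rkPos <- rankMetrics(mk("GMSD", 1))$ranking
  set.seed(42)
  rkNeg <- rankMetrics(mk("GMSD", -1))$ranking
  expect_equal(rkPos$SC, rkNeg$SC)
  expect_equal(rkPos$NMD, rkNeg$NMD)
  expect_equal(rkPos$CS, rkNeg$CS)
})

test_that("Spearman against quality rank hits its sign conventions", {
  # one image per subset: no rank ties, perfect monotone correlation
  s <- mkScores(c(1, 10, 20), c("a", "b", "c"))
  expect_equal(spearmanVsQuality(s), 1.0)
  s$value <- -s$value
  expect_equal(spearmanVsQuality(s), -1.0)
  set.seed(43)
  sr <- mkScores(rnorm(200), rep(paste0("s", 1:4), each = 50))
  expect_lt(abs(spearmanVsQuality(sr)), 0.2)
  sc <- mkScores(rep(1, 20), rep(c("a", "b"), each = 10))
  expect_warning(v <- spearmanVsQuality(sc), "constant")
  expect_equal(v, 0)
})

test_that("Bonferroni option tightens the significance rule", {
  set.seed(44)
  s <- do.call(rbind, lapply(1:4, function(i)
    data.frame(dataset = "d", metric = "SSIM", subset = paste0("s", i),
               quality_rank = i, value = rnorm(8, i * 0.05, 0.05))))
  raw <- rankMetrics(s)$ranking
  bon <- rankMetrics(s, bonferroni = TRUE)$ranking
  expect_lte(bon$SC, raw$SC)
})
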