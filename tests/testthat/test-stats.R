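mkTable <- function(subject, region, fa, adc = fa, tmax = fa) {
  data.frame(subject = subject, region = region, voxel = seq_along(fa),
             fa = fa, adc = adc, tmax = tmax)
}

test_that("summarizeRegions computes arithmetic person-region means", {
  vt <- mkTable(c(1, 1, 1, 2), c("a", "a", "b", "a"),
                fa = c(0.3, 0.4, 0.5, 0.7), adc = c(1, 2, 3, 4),
                tmax = c(10, 20, 30, 40))
  s <- summarizeRegions(vt)
  expect_equal(nrow(s), 3L)
  expect_equal(s$meanFa[s$subject == 1 & s$region == "a"], 0.35)
  expect_equal(s$meanAdc[s$subject == 1 & s$region == "a"], 1.5)
  expect_equal(s$nVoxels[s$subject == 1 & s$region == "a"], 2L)
  # single-voxel region: the mean is that value
  expect_equal(s$meanFa[s$subject == 1 & s$region == "b"], 0.5)
  # subject 2 has no region b: the row is absent, not zero
  expect_false(any(s$subject == 2 & s$region == "b"))
  expect_equal(nrow(summarizeRegions(vt[0, ])), 0L)
})

test_that("rmAnova matches hand-computed sums of squares and aov", {
  # 4 subjects x 3 regions, hand-checkable numbers
  y <- matrix(c(10, 12, 14,
                11, 14, 15,
                 9, 11, 15,
                12, 13, 18), 4, 3, byrow = TRUE)
  s <- data.frame(subject = rep(1:4, each = 3),
                  region = rep(c("r1", "r2", "r3"), 4),
                  meanFa = as.numeric(t(y)))
  a <- rmAnova(s, "meanFa")

  # independent sums-of-squares oracle
  grand <- mean(y)
  ssRegion <- 4 * sum((colMeans(y) - grand)^2)
  ssSubject <- 3 * sum((rowMeans(y) - grand)^2)
  ssError <- sum((y - grand)^2) - ssRegion - ssSubject
  fOracle <- (ssRegion / 2) / (ssError / 6)
  expect_equal(a@statistic, fOracle, tolerance = 1e-10)
  expect_equal(a@df, c(2, 6))

  # cross-check against aov with a subject stratum
  fit <- stats::aov(meanFa ~ region + Error(factor(subject)), data = s)
  tab <- summary(fit)[["Error: Within"]][[1]]
  expect_equal(a@statistic, tab["region", "F value"], tolerance = 1e-10)
  expect_equal(a@pValue, tab["region", "Pr(>F)"], tolerance = 1e-10)

  # Tukey cross-check against TukeyHSD on the equivalent two-way fit
  fit2 <- stats::aov(meanFa ~ region + factor(subject), data = s)
  tk <- stats::TukeyHSD(fit2, "region")$region
  for (i in seq_len(nrow(a@pairwise))) {
    key <- paste(a@pairwise$region2[i], a@pairwise$region1[i], sep = "-")
    expect_equal(a@pairwise$pTukey[i], tk[key, "p adj"], tolerance = 1e-8)
    expect_equal(a@pairwise$meanDiff[i], -tk[key, "diff"], tolerance = 1e-10)
  }
})

test_that("rmAnova is invariant to per-subject shifts and handles degeneracies", {
  set.seed(3)
  s <- data.frame(subject = rep(1:6, each = 3),
                  region = rep(c("a", "b", "c"), 6),
                  meanFa = rnorm(18))
  a1 <- rmAnova(s, "meanFa")
  s2 <- s
  s2$meanFa <- s$meanFa + rep(rnorm(6, 0, 10), each = 3)  # subject effects
  a2 <- rmAnova(s2, "meanFa")
  expect_equal(a1@statistic, a2@statistic, tolerance = 1e-8)

  # identical region values per subject: F = 0, p = 1
  s3 <- data.frame(subject = rep(1:4, each = 3),
                   region = rep(c("a", "b", "c"), 4),
                   meanFa = rep(rnorm(4), each = 3))
  a3 <- rmAnova(s3, "meanFa")
  expect_equal(a3@statistic, 0)
  expect_equal(a3@pValue, 1)

  # zero error mean square with a real effect: flagged, p at machine floor
  s4 <- data.frame(subject = rep(1:4, each = 3),
                   region = rep(c("a", "b", "c"), 4),
                   meanFa = rep(c(1, 2, 3), 4))
  a4 <- rmAnova(s4, "meanFa")
  expect_true(a4@zeroErrorFlag)
  expect_lt(a4@pValue, 1e-300)

  # incomplete subjects dropped with a warning; too few subjects error
  s5 <- rbind(s3, data.frame(subject = 9, region = "a", meanFa = 1))
  expect_warning(rmAnova(s5, "meanFa"), "dropped")
  expect_error(rmAnova(s3[s3$subject <= 2, ], "meanFa"), "3")
})

test_that("spearmanCor matches the rank-then-Pearson oracle, ties included", {
  expect_equal(spearmanCor(1:3, c(3, 5, 9))$rho, 1)
  expect_equal(spearmanCor(1:3, c(9, 5, 3))$rho, -1)

  set.seed(9)
  x <- sample(1:5, 30, replace = TRUE)     # heavy ties
  y <- x + rnorm(30)
  sp <- spearmanCor(x, y)
  expect_equal(sp$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)

  # t-approximation p-value oracle
  tstat <- sp$rho * sqrt((30 - 2) / (1 - sp$rho^2))
  expect_equal(sp$pValue, 2 * pt(abs(tstat), 28, lower.tail = FALSE))

  d <- spearmanCor(rep(1, 5), 1:5)
  expect_true(d$degenerate)
  expect_true(is.na(d$rho))
  expect_error(spearmanCor(1:2, 1:2), "3")
})

test_that("bestSplit reproduces the worked example and honors tie-breaks", {
  s <- bestSplit(c(1, 2, 3, 10, 11), c(0.30, 0.31, 0.29, 0.40, 0.41),
                 minGroupSize = 2L, nPermutations = 0L)
  expect_equal(s@threshold, 6.5)
  expect_equal(s@meanLow, 0.30)
  expect_equal(s@meanHigh, 0.405)
  expect_equal(s@meanDifference, 0.105)
  expect_equal(s@nLow, 3L)
  expect_equal(s@nHigh, 2L)

  # constant FA: every split ties, the smallest candidate wins, p ~ 1
  s2 <- bestSplit(c(1, 2, 3, 4, 5, 6), rep(0.4, 6), minGroupSize = 2L,
                  nPermutations = 99L, seed = 1)
  expect_equal(s2@threshold, 2.5)     # smallest admissible midpoint
  expect_equal(s2@pValue, 1)

  expect_error(bestSplit(rep(2, 10), rnorm(10)), "distinct")
  expect_error(bestSplit(1:3, rnorm(3), minGroupSize = 2L), "observations")
})

test_that("bestSplit equals the exhaustive oracle on random instances", {
  oracle <- function(tmax, fa, mg) {
    cand <- sort(unique(tmax))
    thr <- (cand[-1] + cand[-length(cand)]) / 2
    best <- NULL
    for (th in thr) {
      lo <- fa[tmax < th]; hi <- fa[tmax >= th]
      if (length(lo) < mg || length(hi) < mg) next
      sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
      if (is.null(best) || sse < best$sse - 1e-12) best <- list(th = th, sse = sse)
    }
    best
  }
  set.seed(31)
  for (n in c(5, 12, 40, 200)) {
    for (rep in 1:3) {
      tmax <- round(runif(n, 0, 8) / 1.45) * 1.45   # TR-quantized, many ties
      if (length(unique(tmax)) < 2) next
      fa <- 0.35 + 0.05 * (tmax > 4) + rnorm(n, 0, 0.02)
      o <- oracle(tmax, fa, 2L)
      if (is.null(o)) {
        expect_error(bestSplit(tmax, fa, minGroupSize = 2L,
                               nPermutations = 0L), "admissible")
        next
      }
      s <- bestSplit(tmax, fa, minGroupSize = 2L, nPermutations = 0L)
      expect_equal(s@threshold, o$th)
      expect_equal(s@criterion, o$sse, tolerance = 1e-10)
    }
  }
})

test_that("a planted FA step is localized between the straddling Tmax values", {
  set.seed(17)
  tmax <- runif(21, 2, 9)
  fa <- ifelse(tmax >= 5.4, rnorm(21, 0.423, 0.004), rnorm(21, 0.390, 0.004))
  s <- bestSplit(tmax, fa, minGroupSize = 2L, nPermutations = 0L)
  lo <- max(tmax[tmax < 5.4]); hi <- min(tmax[tmax >= 5.4])
  expect_gte(s@threshold, lo)
  expect_lte(s@threshold, hi)
})

test_that("analyzeCohort assembles all report sections", {
  set.seed(23)
  regions <- c("hypoperfused", "infarct_core", "normal_contra")
  s <- expand.grid(subject = 1:8, region = regions,
                   stringsAsFactors = FALSE)
  s$meanFa <- c(rnorm(8, 0.397, 0.02), rnorm(8, 0.313, 0.03),
                rnorm(8, 0.360, 0.02))
  s$meanAdc <- c(rnorm(8, 7.2e-4, 3e-5), rnorm(8, 5e-4, 4e-5),
                 rnorm(8, 7.2e-4, 3e-5))
  s$meanTmax <- c(runif(8, 2, 9), runif(8, 4, 10), runif(8, 0, 2))
  s$nVoxels <- 50L
  vt <- mkTable(rep(1:8, each = 4), rep("hypoperfused", 32),
                fa = rnorm(32, 0.4, 0.02), tmax = runif(32, 2, 9))

  rep1 <- analyzeCohort(s, vt, nPermutations = 49L, seed = 2)
  expect_setequal(unique(rep1$regionSummary$measure), c("FA", "ADC", "Tmax"))
  expect_s4_class(rep1$anova$FA, "AnovaResult")
  expect_equal(nrow(rep1$correlations), 9L)
  expect_s4_class(rep1$split, "SplitResult")
  expect_equal(rep1$splitUnit, "person")
  expect_setequal(rep1$subgroupMeans$region, c("hypoperfused", "infarct_core"))

  rep2 <- analyzeCohort(s, vt, splitUnit = "voxel", nPermutations = 49L,
                        seed = 2)
  expect_equal(rep2$splitUnit, "voxel")
  expect_equal(rep2$split@nLow + rep2$split@nHigh, 32L)

  expect_error(analyzeCohort(s[s$subject <= 2, ], vt), "3 subjects")
  expect_error(analyzeCohort(s, NULL, splitUnit = "voxel"), "voxel table")
})
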