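#' Person-region summaries of voxel tables
#'
#' Arithmetic means of FA, ADC and Tmax across a region's voxels for each
#' subject, the unit of all downstream statistics. Subject-region cells
#' with no voxels are simply absent from the output (never reported as
#' zero).
#'
#' @param voxelTable data.frame as produced by [extractValues()] (possibly
#'   row-bound over subjects).
#' @return data.frame with columns `subject`, `region`, `meanFa`, `meanAdc`,
#'   `meanTmax`, `nVoxels`.
#' @export
summarizeRegions <- function(voxelTable) {
  if (!nrow(voxelTable))
    return(data.frame(subject = integer(), region = character(),
                      meanFa = numeric(), meanAdc = numeric(),
                      meanTmax = numeric(), nVoxels = integer()))
  key <- interaction(voxelTable$subject, voxelTable$region, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  first <- !duplicated(key)
  ord <- order(voxelTable$subject[first], voxelTable$region[first])
  out <- data.frame(
    subject = voxelTable$subject[first],
    region = voxelTable$region[first],
    meanFa = as.numeric(agg(voxelTable$fa)[levels(key)[key[first]]]),
    meanAdc = as.numeric(agg(voxelTable$adc)[levels(key)[key[first]]]),
    meanTmax = as.numeric(agg(voxelTable$tmax)[levels(key)[key[first]]]),
    nVoxels = as.integer(table(key)[levels(key)[key[first]]])
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA across regions with Tukey pairwise comparisons
#'
#' Classical one-way within-subject ANOVA on person-region means:
#' \eqn{F = MS_{region} / MS_{error}} with degrees of freedom
#' \eqn{(k-1)} and \eqn{(k-1)(n-1)}, where the error stratum is the
#' subject-by-region interaction. Pairwise comparisons use the Tukey HSD:
#' studentized-range p-values based on \eqn{MS_{error}} and its degrees of
#' freedom. Subjects missing any region are dropped (complete-case) with a
#' warning.
#'
#' @param summaries data.frame from [summarizeRegions()].
#' @param value which measure to analyze: `"meanFa"`, `"meanAdc"` or
#'   `"meanTmax"` (or any numeric column of `summaries`).
#' @return An [AnovaResult-class].
#' @export
rmAnova <- function(summaries, value = "meanFa") {
  if (!value %in% names(summaries)) stop("no column called ", value)
  regions <- sort(unique(summaries$region))
  k <- length(regions)
  if (k < 2L) stop("need at least two regions")
  wide <- tapply(summaries[[value]],
                 list(summaries$subject, summaries$region), mean)
  complete <- rowSums(is.na(wide)) == 0L
  if (any(!complete))
    warning(sum(!complete), " subject(s) missing a region were dropped")
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  if (n < 3L) stop("repeated-measures ANOVA needs at least 3 complete subjects")

  grand <- mean(wide)
  regMeans <- colMeans(wide)
  subjMeans <- rowMeans(wide)
  ssRegion <- n * sum((regMeans - grand)^2)
  ssSubject <- k * sum((subjMeans - grand)^2)
  ssTotal <- sum((wide - grand)^2)
  ssError <- ssTotal - ssRegion - ssSubject
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  msRegion <- ssRegion / df1
  msError <- max(ssError, 0) / df2

  zero <- msError <= .Machine$double.eps * max(1, msRegion)
  if (zero) {
    f <- if (msRegion > 0) Inf else 0
    p <- if (msRegion > 0) .Machine$double.xmin else 1
  } else {
    f <- msRegion / msError
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(regions, 2)
  se <- sqrt(msError / n)
  pw <- data.frame(
    region1 = pairs[1, ], region2 = pairs[2, ],
    meanDiff = regMeans[pairs[1, ]] - regMeans[pairs[2, ]],
    pTukey = NA_real_
  )
  for (i in seq_len(ncol(pairs))) {
    q <- abs(pw$meanDiff[i]) / se
    pw$pTukey[i] <- if (zero) {
      if (abs(pw$meanDiff[i]) > 0) .Machine$double.xmin else 1
    } else stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
  }
  rownames(pw) <- NULL
  new("AnovaResult", statistic = unname(f), df = c(df1, df2),
      pValue = unname(p), msError = msError, nSubjects = as.integer(n),
      pairwise = pw, zeroErrorFlag = zero)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks with average tie handling, Pearson correlation of the ranks, and a
#' two-sided p-value from \eqn{t = r_s\sqrt{(n-2)/(1-r_s^2)}} on
#' \eqn{n - 2} degrees of freedom. Degenerate inputs (zero rank variance)
#' give `NA` with a flag.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return list with `rho`, `pValue`, `n`, and `degenerate`.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, pValue = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, pValue = p, n = n, degenerate = FALSE)
}

# Core of the split search: total within-group SSE for every candidate
# threshold (midpoints between consecutive distinct sorted tmax values),
# honoring the minimum group size. Returns NULL when no admissible split
# exists. O(n log n) via prefix sums.
splitCriterion <- function(tmax, fa, minGroupSize) {
  ord <- order(tmax)
  ts <- tmax[ord]; fs <- fa[ord]
  n <- length(ts)
  bnd <- which(diff(ts) > 0)            # split after position bnd
  if (!length(bnd)) return(NULL)
  keep <- bnd >= minGroupSize & (n - bnd) >= minGroupSize
  bnd <- bnd[keep]
  if (!length(bnd)) return(NULL)
  cs <- cumsum(fs); cs2 <- cumsum(fs^2)
  nl <- bnd; nh <- n - bnd
  sl <- cs[bnd]; sh <- cs[n] - sl
  ssl <- cs2[bnd]; ssh <- cs2[n] - ssl
  sse <- (ssl - sl^2 / nl) + (ssh - sh^2 / nh)
  list(
    threshold = (ts[bnd] + ts[bnd + 1L]) / 2,
    sse = sse, nLow = nl, nHigh = nh,
    meanLow = sl / nl, meanHigh = sh / nh
  )
}

#' Single-split regression-tree search on Tmax
#'
#' Exhaustive search over candidate thresholds (midpoints between
#' consecutive distinct sorted Tmax values) for the split minimizing the
#' total within-group sum of squared FA deviations — i.e. the residual
#' variance of a one-split regression tree. Ties in the criterion break
#' toward the smaller threshold. The primary p-value is a selection-aware
#' permutation test: FA values are permuted against Tmax and the full
#' search re-run for each permutation, so the reference distribution
#' accounts for threshold selection. A Welch t-test on the selected groups
#' is reported as a secondary, uncorrected p-value.
#'
#' @param tmax,fa numeric vectors (seconds; dimensionless FA).
#' @param minGroupSize minimum size of each subgroup (default 2).
#' @param nPermutations permutations for the p-value (default 10000; 0
#'   skips the test, `pValue` is then `NA`).
#' @param seed optional seed for the permutation draw.
#' @return A [SplitResult-class].
#' @export
bestSplit <- function(tmax, fa, minGroupSize = 2L, nPermutations = 10000L,
                      seed = NULL) {
  ok <- is.finite(tmax) & is.finite(fa)
  tmax <- tmax[ok]; fa <- fa[ok]
  n <- length(tmax)
  if (n < 2L * minGroupSize)
    stop("need at least 2 * minGroupSize observations")
  if (length(unique(tmax)) < 2L)
    stop("need at least 2 distinct Tmax values to split")
  cand <- splitCriterion(tmax, fa, minGroupSize)
  if (is.null(cand))
    stop("no admissible split honors the minimum group size")
  # ties in the criterion (within numerical round-off) break toward the
  # smaller threshold; candidates are already in ascending threshold order
  eps <- 1e-10 * (sum(fa^2) + 1)
  best <- which(cand$sse <= min(cand$sse) + eps)[1]
  obs <- cand$sse[best]

  pperm <- NA_real_
  if (nPermutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      cb <- splitCriterion(tmax, sample(fa), minGroupSize)
      if (!is.null(cb) && min(cb$sse) <= obs + eps) hits <- hits + 1L
    }
    pperm <- (1 + hits) / (nPermutations + 1)
  }

  lo <- fa[tmax < cand$threshold[best]]
  hi <- fa[tmax >= cand$threshold[best]]
  pWelch <- if (stats::sd(lo) == 0 && stats::sd(hi) == 0) {
    if (mean(hi) == mean(lo)) 1 else 0
  } else tryCatch(stats::t.test(hi, lo)$p.value, error = function(e) NA_real_)

  new("SplitResult",
      threshold = cand$threshold[best],
      nLow = as.integer(cand$nLow[best]), nHigh = as.integer(cand$nHigh[best]),
      meanLow = cand$meanLow[best], meanHigh = cand$meanHigh[best],
      meanDifference = cand$meanHigh[best] - cand$meanLow[best],
      pValue = pperm, pWelch = pWelch, criterion = obs,
      nPermutations = as.integer(nPermutations))
}

#' Full cohort analysis report
#'
#' Assembles the cohort-level results from person-region summaries:
#' \itemize{
#'   \item `regionSummary`: mean and SD per region for each measure;
#'   \item `anova`: repeated-measures ANOVA + Tukey pairwise comparisons
#'     per measure;
#'   \item `correlations`: Spearman correlations of FA-ADC, ADC-Tmax and
#'     FA-Tmax within each region (person-level);
#'   \item `split`: single-split Tmax search on hypoperfused-WM FA, at the
#'     person level by default (`splitUnit = "voxel"` uses the pooled voxel
#'     table instead), plus subgroup FA means above/below the found
#'     threshold in both hypoperfused and infarcted WM.
#' }
#'
#' @param summaries data.frame from [summarizeRegions()].
#' @param voxelTable optional pooled voxel table (required for
#'   `splitUnit = "voxel"`).
#' @param splitUnit `"person"` (default) or `"voxel"`.
#' @param minGroupSize,nPermutations,seed passed to [bestSplit()].
#' @return list with the four report sections.
#' @export
analyzeCohort <- function(summaries, voxelTable = NULL,
                          splitUnit = c("person", "voxel"),
                          minGroupSize = 2L, nPermutations = 10000L,
                          seed = NULL) {
  splitUnit <- match.arg(splitUnit)
  if (length(unique(summaries$subject)) < 3L)
    stop("cohort analysis needs at least 3 subjects")
  measures <- c(FA = "meanFa", ADC = "meanAdc", Tmax = "meanTmax")

  regionSummary <- do.call(rbind, lapply(names(measures), function(m) {
    v <- summaries[[measures[m]]]
    data.frame(
      measure = m,
      region = sort(unique(summaries$region)),
      mean = as.numeric(tapply(v, summaries$region, mean)),
      sd = as.numeric(tapply(v, summaries$region, stats::sd))
    )
  }))

  anova <- lapply(measures, function(col) rmAnova(summaries, col))

  regions <- sort(unique(summaries$region))
  pairsOf <- list(c("meanFa", "meanAdc"), c("meanAdc", "meanTmax"),
                  c("meanFa", "meanTmax"))
  correlations <- do.call(rbind, lapply(regions, function(rg) {
    sub <- summaries[summaries$region == rg, ]
    do.call(rbind, lapply(pairsOf, function(pr) {
      sp <- spearmanCor(sub[[pr[1]]], sub[[pr[2]]])
      data.frame(region = rg,
                 pair = paste(sub("mean", "", pr[1]), sub("mean", "", pr[2]),
                              sep = "-"),
                 rho = sp$rho, pValue = sp$pValue, n = sp$n)
    }))
  }))

  hypo <- summaries[summaries$region == "hypoperfused", ]
  split <- NULL
  subgroupMeans <- NULL
  if (splitUnit == "person") {
    if (nrow(hypo) >= 2L * minGroupSize && length(unique(hypo$meanTmax)) >= 2L)
      split <- bestSplit(hypo$meanTmax, hypo$meanFa, minGroupSize,
                         nPermutations, seed)
  } else {
    if (is.null(voxelTable))
      stop("splitUnit = 'voxel' needs the voxel table")
    hv <- voxelTable[voxelTable$region == "hypoperfused", ]
    split <- bestSplit(hv$tmax, hv$fa, minGroupSize, nPermutations, seed)
  }
  if (!is.null(split)) {
    thr <- split@threshold
    subgroupMeans <- do.call(rbind, lapply(
      c("hypoperfused", "infarct_core"), function(rg) {
        sub <- summaries[summaries$region == rg, ]
        data.frame(
          region = rg,
          group = c("belowThreshold", "aboveThreshold"),
          meanFa = c(mean(sub$meanFa[sub$meanTmax < thr]),
                     mean(sub$meanFa[sub$meanTmax >= thr])),
          n = c(sum(sub$meanTmax < thr), sum(sub$meanTmax >= thr))
        )
      }))
  }

  list(regionSummary = regionSummary, anova = anova,
       correlations = correlations, split = split,
       subgroupMeans = subgroupMeans, splitUnit = splitUnit)
}
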