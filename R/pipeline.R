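#' Run the voxel-based analysis for one subject
#'
#' Executes the per-subject stages on in-memory inputs sharing one voxel
#' grid: tensor fit and FA/ADC maps, concentration conversion and
#' block-circulant SVD deconvolution to a Tmax map, threshold segmentation,
#' and voxel-value extraction.
#'
#' @param dwi 4-D DWI array.
#' @param scheme an [AcquisitionScheme-class].
#' @param dsc 4-D DSC signal array.
#' @param aif arterial input concentration curve (length = DSC timepoints).
#' @param contraRoi logical array: contralateral normal-WM ROI.
#' @param perfusionRoi logical array, or `NULL` to derive it with
#'   [autoPerfusionRoi()] from the Tmax map.
#' @param config validated configuration list
#'   (see [defaultPipelineConfig()]).
#' @param subject subject identifier for the voxel table.
#' @param brainMask logical array; default: voxels with positive signal in
#'   the first DWI volume.
#' @param voxelSize voxel dimensions in mm.
#' @return list with `fa`, `adc`, `tmax` ([ScalarMap-class]), `masks`
#'   ([RegionMasks-class]), `perfusionRoi`, and `voxelTable`.
#' @export
runSubject <- function(dwi, scheme, dsc, aif, contraRoi, perfusionRoi = NULL,
                       config = defaultPipelineConfig(), subject = 1L,
                       brainMask = NULL, voxelSize = c(1.5, 1.5, 3)) {
  dims <- dim(dwi)[1:3]
  if (!identical(dim(dsc)[1:3], dims))
    stop("DWI and DSC are not on the same voxel grid")
  if (is.null(brainMask)) {
    b0 <- dwi[, , , 1]
    brainMask <- is.finite(b0) & b0 > 0
  }
  maps <- computeMaps(dwi, scheme, brainMask, voxelSize)

  n <- dscTimepoints(scheme)
  if (dim(dsc)[4] != n)
    stop("DSC series length does not match the scheme")
  sig <- matrix(dsc, prod(dims), n)
  conc <- signalToConcentration(t(sig[brainMask, , drop = FALSE]),
                                dscTE(scheme), 8L)
  resid <- deconvolveOsvd(conc, aif, dscTR(scheme),
                          config$deconvolution$thresholdFrac)
  tmax <- tmaxMap(resid, brainMask, dscTR(scheme), n,
                  config$deconvolution$interpolateTmax, voxelSize)

  if (is.null(perfusionRoi))
    perfusionRoi <- autoPerfusionRoi(tmax, contraRoi,
                                     config$thresholds$tmaxRoiK,
                                     dscTR(scheme))
  masks <- segmentRegions(maps$fa, maps$adc, perfusionRoi, contraRoi,
                          config$thresholds$faWm, config$thresholds$adcCore,
                          config$segmentation$coreWithinRoi)
  vt <- extractValues(masks, maps$fa, maps$adc, tmax, subject)
  list(fa = maps$fa, adc = maps$adc, tmax = tmax, masks = masks,
       perfusionRoi = perfusionRoi, voxelTable = vt)
}

readSubjectBundle <- function(dir) {
  vol <- function(f, ndim = NULL) readVolume(file.path(dir, f), ndim)
  list(
    dwi = vol("dwi.nii.gz", 4L),
    dsc = vol("dsc.nii.gz", 4L),
    aif = scan(file.path(dir, "aif.txt"), quiet = TRUE),
    perfusionRoi = vol("perfusion_roi.nii.gz", 3L)$data > 0,
    contraRoi = vol("contra_roi.nii.gz", 3L)$data > 0,
    bval = file.path(dir, "dwi.bval"),
    bvec = file.path(dir, "dwi.bvec")
  )
}

#' Run the full cohort pipeline on a directory of subject bundles
#'
#' Processes every `sub-*` directory under `cohortDir` (the layout written
#' by [generateCohort()]): per subject, [runSubject()]; then
#' [summarizeRegions()] and [analyzeCohort()]. Each threshold applied and
#' the voxel counts surviving each stage are logged via `message()`. If
#' `outDir` is given, the summary tables, the report and a provenance block
#' (configuration hash, seed, package and R versions) are written as
#' TSV/JSON.
#'
#' @param cohortDir directory containing `sub-*` bundles.
#' @param config configuration list or path to a YAML file.
#' @param outDir optional output directory for the report files.
#' @param useSuppliedRoi use each bundle's `perfusion_roi.nii.gz` when
#'   present (default `TRUE`); otherwise the ROI is derived from the Tmax
#'   map.
#' @return list with `summaries`, `voxelTable`, `report` and `provenance`.
#' @export
runPipeline <- function(cohortDir, config = defaultPipelineConfig(),
                        outDir = NULL, useSuppliedRoi = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- validateConfig(config)
  dirs <- sort(list.dirs(cohortDir, recursive = FALSE))
  dirs <- dirs[grepl("sub-", basename(dirs))]
  if (!length(dirs)) stop("no subject bundles (sub-*) found in ", cohortDir)
  message(sprintf("pipeline: %d subjects; FA>%g WM mask, ADC<%g core, %s Tmax",
                  length(dirs), config$thresholds$faWm,
                  config$thresholds$adcCore,
                  if (config$deconvolution$interpolateTmax)
                    "interpolated" else "grid"))
  tables <- vector("list", length(dirs))
  for (i in seq_along(dirs)) {
    bundle <- readSubjectBundle(dirs[i])
    scheme <- readGradients(bundle$bval, bundle$bvec,
                            dscNTimepoints = dim(bundle$dsc$data)[4])
    res <- runSubject(bundle$dwi$data, scheme, bundle$dsc$data, bundle$aif,
                      bundle$contraRoi,
                      if (useSuppliedRoi) bundle$perfusionRoi else NULL,
                      config, subject = i,
                      voxelSize = bundle$dwi$voxelSize)
    m <- res$masks
    message(sprintf(
      "  %s: wm %d | core %d | hypoperfused %d | contra %d voxels (%d rows dropped)",
      basename(dirs[i]), sum(m@wm), sum(m@infarctCore), sum(m@hypoperfused),
      sum(m@normalContra), attr(res$voxelTable, "dropped")))
    tables[[i]] <- res$voxelTable
  }
  voxelTable <- do.call(rbind, tables)
  summaries <- summarizeRegions(voxelTable)
  set.seed(config$seed)
  report <- analyzeCohort(summaries, voxelTable,
                          splitUnit = config$statistics$splitUnit,
                          minGroupSize = config$statistics$minGroupSize,
                          nPermutations = config$statistics$nPermutations)
  provenance <- list(
    configHash = configHash(config), seed = config$seed,
    package = as.character(utils::packageVersion("wmIschemia")),
    rVersion = R.version.string, nSubjects = length(dirs)
  )
  if (!is.null(outDir)) writeReport(report, summaries, provenance, outDir)
  list(summaries = summaries, voxelTable = voxelTable, report = report,
       provenance = provenance)
}

#' Write a cohort report to disk
#'
#' @param report list from [analyzeCohort()].
#' @param summaries person-region summary table.
#' @param provenance provenance list (configuration hash, seed, versions).
#' @param outDir output directory, created if needed.
#' @return Invisibly, the output directory.
#' @export
writeReport <- function(report, summaries, provenance, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(outDir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(summaries, "person_region_summaries.tsv")
  tsv(report$regionSummary, "region_summary.tsv")
  pw <- do.call(rbind, lapply(names(report$anova), function(m)
    cbind(measure = m, report$anova[[m]]@pairwise)))
  tsv(pw, "pairwise_tukey.tsv")
  tsv(report$correlations, "spearman_correlations.tsv")
  if (!is.null(report$subgroupMeans)) tsv(report$subgroupMeans, "split_subgroups.tsv")
  js <- list(
    provenance = provenance,
    anova = lapply(report$anova, function(a) list(
      F = a@statistic, df = a@df, p = a@pValue, n = a@nSubjects)),
    split = if (!is.null(report$split)) {
      s <- report$split
      list(threshold = s@threshold, meanLow = s@meanLow, meanHigh = s@meanHigh,
           meanDifference = s@meanDifference, pPermutation = s@pValue,
           pWelch = s@pWelch, nLow = s@nLow, nHigh = s@nHigh,
           unit = report$splitUnit)
    }
  )
  jsonlite::write_json(js, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
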