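#' @import methods
NULL

#' Diffusion and perfusion acquisition scheme
#'
#' Describes one combined DTI + DSC acquisition: a per-volume gradient table
#' for the diffusion series (b-values and unit gradient directions, b = 0
#' rows for the non-diffusion-weighted volumes) and the repetition/echo time
#' and length of the dynamic susceptibility contrast (DSC) series.
#'
#' @slot gradientTable data.frame with one row per DWI volume and columns
#'   `bval` (s/mm^2), `gx`, `gy`, `gz` (unit direction; zeros for b = 0 rows).
#' @slot dscTR repetition time of the DSC series, seconds.
#' @slot dscTE echo time of the DSC series, seconds.
#' @slot dscNTimepoints number of DSC repetitions.
#'
#' @seealso [defaultScheme()], [readGradients()]
#' @export
setClass("AcquisitionScheme",
  slots = c(
    gradientTable = "data.frame",
    dscTR = "numeric",
    dscTE = "numeric",
    dscNTimepoints = "integer"
  )
)

setValidity("AcquisitionScheme", function(object) {
  gt <- object@gradientTable
  msg <- character()
  if (!all(c("bval", "gx", "gy", "gz") %in% names(gt)))
    msg <- c(msg, "gradientTable must have columns bval, gx, gy, gz")
  else {
    dw <- gt$bval > 0
    if (!any(dw)) msg <- c(msg, "at least one diffusion-weighted volume required")
    if (!any(!dw)) msg <- c(msg, "at least one b = 0 volume required")
    if (any(dw)) {
      nrm <- sqrt(gt$gx[dw]^2 + gt$gy[dw]^2 + gt$gz[dw]^2)
      if (any(abs(nrm - 1) > 1e-8))
        msg <- c(msg, "diffusion-weighted directions must have unit norm (within 1e-8)")
    }
    if (any(gt$bval < 0)) msg <- c(msg, "b-values must be nonnegative")
  }
  if (length(object@dscTR) != 1L || object@dscTR <= 0)
    msg <- c(msg, "dscTR must be a positive scalar")
  if (length(object@dscTE) != 1L || object@dscTE <= 0)
    msg <- c(msg, "dscTE must be a positive scalar")
  if (object@dscNTimepoints < 10L)
    msg <- c(msg, "dscNTimepoints must be >= 10")
  if (length(msg)) msg else TRUE
})

#' Construct an acquisition scheme
#'
#' @param directions n x 3 matrix of diffusion gradient directions (need not
#'   be exactly unit norm; they are normalized).
#' @param bValue diffusion weighting in s/mm^2, applied to every direction.
#' @param nB0 number of b = 0 volumes, placed first in the volume order.
#' @param dscTR,dscTE DSC repetition and echo time in seconds.
#' @param dscNTimepoints number of DSC repetitions.
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' sch <- defaultScheme()
#' nrow(gradientTable(sch))   # 21: one b=0 plus 20 directions
#' @export
AcquisitionScheme <- function(directions, bValue = 1000, nB0 = 1L,
                              dscTR = 1.45, dscTE = 0.022,
                              dscNTimepoints = 60L) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) stop("zero-length gradient direction")
  directions <- directions / nrm
  gt <- data.frame(
    bval = c(rep(0, nB0), rep(bValue, nrow(directions))),
    gx = c(rep(0, nB0), directions[, 1]),
    gy = c(rep(0, nB0), directions[, 2]),
    gz = c(rep(0, nB0), directions[, 3])
  )
  new("AcquisitionScheme", gradientTable = gt, dscTR = dscTR, dscTE = dscTE,
      dscNTimepoints = as.integer(dscNTimepoints))
}

#' Scalar parameter map on a voxel grid
#'
#' A single 3-D quantitative map (FA, ADC or Tmax) together with its voxel
#' dimensions. Values are `NA` outside the brain mask. Validity enforces the
#' physical ranges: FA in \[0, 1\], ADC >= 0, Tmax >= 0.
#'
#' @slot data 3-D numeric array.
#' @slot voxelSize voxel edge lengths in mm, length 3.
#' @slot kind one of `"FA"` (dimensionless), `"ADC"` (mm^2/s), `"Tmax"` (s).
#' @export
setClass("ScalarMap",
  slots = c(data = "array", voxelSize = "numeric", kind = "character")
)

setValidity("ScalarMap", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (!object@kind %in% c("FA", "ADC", "Tmax"))
    msg <- c(msg, "kind must be one of FA, ADC, Tmax")
  v <- object@data[is.finite(object@data)]
  if (object@kind == "FA" && length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msg <- c(msg, "FA values must lie in [0, 1]")
  if (object@kind %in% c("ADC", "Tmax") && length(v) && min(v) < -1e-12)
    msg <- c(msg, paste(object@kind, "values must be nonnegative"))
  if (length(msg)) msg else TRUE
})

#' @rdname ScalarMap-class
#' @param data 3-D numeric array.
#' @param voxelSize voxel dimensions in mm (length 3).
#' @param kind map kind: `"FA"`, `"ADC"` or `"Tmax"`.
#' @export
ScalarMap <- function(data, voxelSize = c(1.5, 1.5, 3), kind) {
  new("ScalarMap", data = data, voxelSize = as.numeric(voxelSize), kind = kind)
}

#' Segmentation masks for the white-matter regions
#'
#' Boolean voxel masks produced by [segmentRegions()]: the white-matter mask
#' and the three analysis regions. Validity enforces the set relations the
#' segmentation rules guarantee: infarct core and hypoperfused WM are
#' disjoint, both are contained in WM, and the contralateral normal-WM
#' region is WM and disjoint from the two lesion regions.
#'
#' @slot wm,infarctCore,hypoperfused,normalContra logical 3-D arrays on one grid.
#' @slot voxelSize voxel dimensions in mm.
#' @export
setClass("RegionMasks",
  slots = c(
    wm = "array", infarctCore = "array", hypoperfused = "array",
    normalContra = "array", voxelSize = "numeric"
  )
)

setValidity("RegionMasks", function(object) {
  msg <- character()
  dims <- dim(object@wm)
  for (s in c("infarctCore", "hypoperfused", "normalContra"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, sprintf("%s is not on the same grid as wm", s))
  if (length(msg)) return(msg)
  if (any(object@infarctCore & object@hypoperfused))
    msg <- c(msg, "infarct core and hypoperfused masks overlap")
  if (any((object@infarctCore | object@hypoperfused) & !object@wm))
    msg <- c(msg, "lesion masks must be contained in the WM mask")
  if (any(object@normalContra & !object@wm))
    msg <- c(msg, "contralateral normal-WM mask must be contained in the WM mask")
  if (any(object@normalContra & (object@infarctCore | object@hypoperfused)))
    msg <- c(msg, "contralateral normal-WM mask overlaps a lesion mask")
  if (length(msg)) msg else TRUE
})

#' Digital phantom specification
#'
#' Defines a synthetic multi-subject cohort: the voxel grid, the four tissue
#' compartments with their planted FA / mean-diffusivity / Tmax
#' distributions (between-subject mean and SD plus within-region voxel SD),
#' the DWI noise level, and the DSC forward-model parameters.
#'
#' @slot gridShape integer grid dimensions (x, y, z).
#' @slot voxelSize voxel edge lengths in mm.
#' @slot regions data.frame with one row per compartment and columns `label`,
#'   `faMean`, `faSD`, `mdMean`, `mdSD`, `tmaxMean`, `tmaxSD`, `s0`.
#' @slot snrDwi baseline signal-to-noise ratio of the DWI (Rician noise);
#'   `Inf` for noiseless.
#' @slot dscNoiseSD Gaussian noise SD added to the DSC signal (signal units).
#' @slot nSubjects number of subjects in the cohort.
#' @slot seed base random seed for the cohort.
#' @slot voxelSD named numeric: within-region voxel-to-voxel SD of `fa`,
#'   `md` and `tmax` around each subject's regional value.
#' @slot dscModel list of DSC forward-model constants: gamma-variate AIF
#'   onset/shape/scale/amplitude, tissue mean transit time `mtt` (s),
#'   flow scale `cbf`, number of pre-bolus baseline points `baselineN`, and
#'   SVD truncation `thresholdFrac`.
#' @slot tmaxConvention `"grid"` (arrival delay equals true Tmax; recovery is
#'   exact for TR multiples) or `"interpolated"` (delay calibrated so the
#'   parabolic-interpolated deconvolution recovers the planted continuous
#'   Tmax).
#' @seealso [defaultPhantomSpec()], [generateCohort()]
#' @export
setClass("PhantomSpec",
  slots = c(
    gridShape = "integer", voxelSize = "numeric", regions = "data.frame",
    snrDwi = "numeric", dscNoiseSD = "numeric", nSubjects = "integer",
    seed = "integer", voxelSD = "numeric", dscModel = "list",
    tmaxConvention = "character"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 integers, each >= 8 so every region has voxels")
  need <- c("label", "faMean", "faSD", "mdMean", "mdSD", "tmaxMean", "tmaxSD", "s0")
  if (!all(need %in% names(object@regions)))
    msg <- c(msg, paste("regions must have columns:", paste(need, collapse = ", ")))
  else {
    r <- object@regions
    want <- c("normal_wm", "gray_matter", "hypoperfused_wm", "infarct_core")
    if (!all(want %in% r$label))
      msg <- c(msg, "regions must include normal_wm, gray_matter, hypoperfused_wm, infarct_core")
    if (any(r$faMean < 0 | r$faMean >= 1)) msg <- c(msg, "faMean must satisfy 0 <= faMean < 1")
    if (any(r$mdMean <= 0)) msg <- c(msg, "mdMean must be positive")
    if (any(r$tmaxMean < 0)) msg <- c(msg, "tmaxMean must be nonnegative")
    if (any(r$faSD < 0 | r$mdSD < 0 | r$tmaxSD < 0)) msg <- c(msg, "SDs must be nonnegative")
    if (any(r$s0 <= 0)) msg <- c(msg, "s0 must be positive")
  }
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (!all(c("fa", "md", "tmax") %in% names(object@voxelSD)))
    msg <- c(msg, "voxelSD must be named with fa, md, tmax")
  if (!object@tmaxConvention %in% c("grid", "interpolated"))
    msg <- c(msg, "tmaxConvention must be 'grid' or 'interpolated'")
  if (length(msg)) msg else TRUE
})

#' Per-subject ground truth maps
#'
#' The planted truth for one simulated subject: a region label map and the
#' true FA, ADC and Tmax per voxel, plus the subject's regional parameter
#' draws.
#'
#' @slot labelMap integer 3-D array; 1 = normal WM, 2 = gray matter,
#'   3 = hypoperfused WM, 4 = infarct core.
#' @slot trueFa,trueAdc,trueTmax numeric 3-D arrays.
#' @slot subjectRegions data.frame of the subject-level regional draws.
#' @export
setClass("GroundTruth",
  slots = c(
    labelMap = "array", trueFa = "array", trueAdc = "array",
    trueTmax = "array", subjectRegions = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  dims <- dim(object@labelMap)
  for (s in c("trueFa", "trueAdc", "trueTmax"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, sprintf("%s is not on the label-map grid", s))
  lab <- object@labelMap > 0
  if (any(lab)) {
    for (s in c("trueFa", "trueAdc", "trueTmax"))
      if (!all(is.finite(slot(object, s)[lab])))
        msg <- c(msg, sprintf("%s has non-finite values inside labeled voxels", s))
  }
  if (length(msg)) msg else TRUE
})

#' Result of a repeated-measures ANOVA across regions
#'
#' One-way within-subject ANOVA of person-region means, with Tukey-adjusted
#' pairwise comparisons computed from the studentized range using the
#' ANOVA error mean square and its degrees of freedom.
#'
#' @slot statistic F statistic (`MS_region / MS_error`).
#' @slot df numerator and denominator degrees of freedom.
#' @slot pValue overall p-value.
#' @slot msError error mean square.
#' @slot nSubjects number of complete-case subjects used.
#' @slot pairwise data.frame with columns `region1`, `region2`, `meanDiff`
#'   (region1 minus region2) and `pTukey`.
#' @slot zeroErrorFlag TRUE when the error mean square was numerically zero
#'   (p reported at the machine floor).
#' @export
setClass("AnovaResult",
  slots = c(
    statistic = "numeric", df = "numeric", pValue = "numeric",
    msError = "numeric", nSubjects = "integer", pairwise = "data.frame",
    zeroErrorFlag = "logical"
  )
)

setValidity("AnovaResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "F statistic must be nonnegative")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of the single-split Tmax search
#'
#' The Tmax threshold minimizing the total within-group sum of squared FA
#' deviations, the two subgroup means, their difference (high minus low),
#' and a selection-aware permutation p-value (a Welch t-test p-value on the
#' selected groups is reported as a secondary, uncorrected quantity).
#'
#' @slot threshold split point in seconds, a midpoint between two observed
#'   Tmax values.
#' @slot nLow,nHigh group sizes.
#' @slot meanLow,meanHigh subgroup FA means.
#' @slot meanDifference `meanHigh - meanLow`.
#' @slot pValue permutation p-value (re-running the full search per permutation).
#' @slot pWelch uncorrected Welch t-test p-value for the selected groups.
#' @slot criterion minimized total within-group sum of squares.
#' @slot nPermutations number of permutations used.
#' @export
setClass("SplitResult",
  slots = c(
    threshold = "numeric", nLow = "integer", nHigh = "integer",
    meanLow = "numeric", meanHigh = "numeric", meanDifference = "numeric",
    pValue = "numeric", pWelch = "numeric", criterion = "numeric",
    nPermutations = "integer"
  )
)

setValidity("SplitResult", function(object) {
  msg <- character()
  if (object@nLow < 1L || object@nHigh < 1L)
    msg <- c(msg, "both subgroups must be nonempty")
  if (abs(object@meanDifference - (object@meanHigh - object@meanLow)) > 1e-10)
    msg <- c(msg, "meanDifference must equal meanHigh - meanLow")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
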