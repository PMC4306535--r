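#' @rdname AcquisitionScheme-class
#' @param object an object.
#' @export
setGeneric("gradientTable", function(object) standardGeneric("gradientTable"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("dwDirections", function(object) standardGeneric("dwDirections"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("bValue", function(object) standardGeneric("bValue"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("nB0", function(object) standardGeneric("nB0"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("dscTR", function(object) standardGeneric("dscTR"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("dscTE", function(object) standardGeneric("dscTE"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("dscTimepoints", function(object) standardGeneric("dscTimepoints"))

#' @rdname ScalarMap-class
#' @param object an object.
#' @export
setGeneric("mapData", function(object) standardGeneric("mapData"))

#' @rdname ScalarMap-class
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))

#' @rdname ScalarMap-class
#' @export
setGeneric("voxelDims", function(object) standardGeneric("voxelDims"))

#' @rdname RegionMasks-class
#' @param object an object.
#' @param region region name: `"wm"`, `"infarct_core"`, `"hypoperfused"` or
#'   `"normal_contra"`.
#' @export
setGeneric("regionMask", function(object, region) standardGeneric("regionMask"))

#' @rdname PhantomSpec-class
#' @param object an object.
#' @export
setGeneric("regionParams", function(object) standardGeneric("regionParams"))

setMethod("gradientTable", "AcquisitionScheme", function(object) object@gradientTable)

setMethod("dwDirections", "AcquisitionScheme", function(object) {
  gt <- object@gradientTable
  as.matrix(gt[gt$bval > 0, c("gx", "gy", "gz")])
})

setMethod("bValue", "AcquisitionScheme", function(object) {
  b <- unique(object@gradientTable$bval)
  max(b)
})

setMethod("nB0", "AcquisitionScheme", function(object)
  sum(object@gradientTable$bval == 0))

setMethod("dscTR", "AcquisitionScheme", function(object) object@dscTR)
setMethod("dscTE", "AcquisitionScheme", function(object) object@dscTE)
setMethod("dscTimepoints", "AcquisitionScheme", function(object) object@dscNTimepoints)

setMethod("mapData", "ScalarMap", function(object) object@data)
setMethod("mapKind", "ScalarMap", function(object) object@kind)
setMethod("voxelDims", "ScalarMap", function(object) object@voxelSize)
setMethod("voxelDims", "RegionMasks", function(object) object@voxelSize)

setMethod("regionMask", "RegionMasks", function(object, region) {
  switch(region,
    wm = object@wm,
    infarct_core = object@infarctCore,
    hypoperfused = object@hypoperfused,
    normal_contra = object@normalContra,
    stop("unknown region: ", region)
  )
})

setMethod("regionParams", "PhantomSpec", function(object) object@regions)

setMethod("show", "AcquisitionScheme", function(object) {
  gt <- object@gradientTable
  cat("AcquisitionScheme\n")
  cat(sprintf("  DWI: %d volumes (%d b=0, %d directions at b=%g s/mm^2)\n",
              nrow(gt), nB0(object), sum(gt$bval > 0), bValue(object)))
  cat(sprintf("  DSC: %d timepoints, TR %.3g s, TE %.3g s\n",
              object@dscNTimepoints, object@dscTR, object@dscTE))
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@data[is.finite(object@data)]
  cat(sprintf("ScalarMap (%s): %s grid, voxel %s mm\n", object@kind,
              paste(dim(object@data), collapse = " x "),
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  if (length(v))
    cat(sprintf("  %d finite voxels, range [%.4g, %.4g], mean %.4g\n",
                length(v), min(v), max(v), mean(v)))
})

setMethod("show", "RegionMasks", function(object) {
  cat("RegionMasks\n")
  cat(sprintf("  wm: %d  infarct_core: %d  hypoperfused: %d  normal_contra: %d voxels\n",
              sum(object@wm), sum(object@infarctCore),
              sum(object@hypoperfused), sum(object@normalContra)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid, %d subjects, DWI SNR %g, seed %d\n",
              paste(object@gridShape, collapse = " x "),
              object@nSubjects, object@snrDwi, object@seed))
  print(object@regions, row.names = FALSE)
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.4g, p = %.3g (n = %d subjects)\n",
              object@df[1], object@df[2], object@statistic, object@pValue,
              object@nSubjects))
  if (object@zeroErrorFlag)
    cat("  note: error mean square numerically zero; p at machine floor\n")
  cat("Tukey-adjusted pairwise comparisons:\n")
  print(object@pairwise, row.names = FALSE)
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("Single-split search: threshold %.3g s\n", object@threshold))
  cat(sprintf("  low  (n=%d): mean %.4g\n", object@nLow, object@meanLow))
  cat(sprintf("  high (n=%d): mean %.4g\n", object@nHigh, object@meanHigh))
  cat(sprintf("  difference %.4g, permutation p = %.4g (B = %d), Welch p = %.4g\n",
              object@meanDifference, object@pValue, object@nPermutations,
              object@pWelch))
})
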