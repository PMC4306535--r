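#' White-matter mask from an FA map
#'
#' A voxel is white matter iff FA is strictly greater than the threshold
#' (default 0.15); the complement acts as the gray-matter mask. Non-finite
#' FA voxels are excluded.
#'
#' @param faMap a [ScalarMap-class] of kind `"FA"`, or a bare numeric array.
#' @param faThreshold FA threshold, in (0, 1).
#' @return Logical array.
#' @export
wmMask <- function(faMap, faThreshold = 0.15) {
  if (faThreshold <= 0 || faThreshold >= 1)
    stop("faThreshold must lie in (0, 1)")
  fa <- if (is(faMap, "ScalarMap")) mapData(faMap) else faMap
  out <- is.finite(fa) & fa > faThreshold
  out[!is.finite(fa)] <- FALSE
  out
}

#' Segment infarcted, hypoperfused and normal white matter
#'
#' Applies the threshold rules on a shared voxel grid:
#' \itemize{
#'   \item infarct core: WM and ADC strictly below `adcCore`
#'     (default 600e-6 mm^2/s);
#'   \item hypoperfused WM: WM, ADC at or above `adcCore`, and inside the
#'     perfusion ROI (ADC exactly at the threshold is assigned to the
#'     hypoperfused side, keeping the partition total);
#'   \item contralateral normal WM: WM inside the contralateral ROI, minus
#'     any lesion voxels.
#' }
#' With the default `coreWithinRoi = TRUE` (the ROI-first workflow) the
#' infarct core is additionally restricted to the perfusion ROI; `FALSE`
#' lets any WM voxel below the ADC threshold join the core.
#'
#' @param faMap,adcMap [ScalarMap-class] objects (or numeric arrays) on one grid.
#' @param perfusionRoi logical array: the perfusion-deficit ROI (hand-drawn
#'   or from [autoPerfusionRoi()]).
#' @param contraRoi logical array: the contralateral normal-WM ROI.
#' @param faThreshold WM mask threshold, see [wmMask()].
#' @param adcCore infarct-core ADC threshold in mm^2/s.
#' @param coreWithinRoi restrict the core to the perfusion ROI (default TRUE).
#' @return A [RegionMasks-class]; its validity object enforces the
#'   disjointness and containment relations.
#' @export
segmentRegions <- function(faMap, adcMap, perfusionRoi, contraRoi,
                           faThreshold = 0.15, adcCore = 600e-6,
                           coreWithinRoi = TRUE) {
  if (adcCore <= 0) stop("adcCore must be positive")
  fa <- if (is(faMap, "ScalarMap")) mapData(faMap) else faMap
  adc <- if (is(adcMap, "ScalarMap")) mapData(adcMap) else adcMap
  vox <- if (is(faMap, "ScalarMap")) voxelDims(faMap) else c(1.5, 1.5, 3)
  dims <- dim(fa)
  for (nm in list(adc = adc, perfusionRoi = perfusionRoi, contraRoi = contraRoi))
    if (!identical(dim(nm), dims))
      stop("all maps and ROIs must share one voxel grid")
  wm <- wmMask(fa, faThreshold)
  adcOk <- is.finite(adc)
  core <- wm & adcOk & (adc < adcCore)
  if (coreWithinRoi) core <- core & perfusionRoi
  hypo <- wm & adcOk & (adc >= adcCore) & as.logical(perfusionRoi)
  contra <- wm & as.logical(contraRoi) & !core & !hypo
  new("RegionMasks", wm = wm, infarctCore = core, hypoperfused = hypo,
      normalContra = contra, voxelSize = as.numeric(vox))
}

#' Operational perfusion-deficit ROI from a Tmax map
#'
#' Reproducible surrogate for a hand-drawn perfusion ROI: voxels whose Tmax
#' exceeds the contralateral mean by more than `k` contralateral SDs. When
#' the contralateral Tmax has zero variance the rule falls back to
#' "greater than the contralateral mean plus one grid step" (`tr` seconds).
#'
#' @param tmaxMap a [ScalarMap-class] of kind `"Tmax"` or a numeric array.
#' @param contraRoi logical array over which the contralateral reference
#'   statistics are taken; must contain finite Tmax voxels.
#' @param k SD multiplier (default 2).
#' @param tr Tmax grid step in seconds, used only by the zero-variance
#'   fallback.
#' @return Logical array.
#' @export
autoPerfusionRoi <- function(tmaxMap, contraRoi, k = 2, tr = 1.45) {
  tm <- if (is(tmaxMap, "ScalarMap")) mapData(tmaxMap) else tmaxMap
  ref <- tm[contraRoi & is.finite(tm)]
  if (!length(ref)) stop("contralateral ROI contains no finite Tmax voxels")
  cut <- if (stats::sd(ref) > 0) mean(ref) + k * stats::sd(ref)
         else mean(ref) + tr
  out <- is.finite(tm) & tm > cut
  out[!is.finite(tm)] <- FALSE
  out
}

#' Extract per-voxel values for every segmented region
#'
#' One row per voxel per region with its FA, ADC and Tmax; rows containing
#' any non-finite value are dropped and counted in the `dropped` attribute.
#'
#' @param masks a [RegionMasks-class].
#' @param faMap,adcMap,tmaxMap [ScalarMap-class] objects or numeric arrays
#'   on the masks' grid.
#' @param subject subject identifier recorded in every row.
#' @return data.frame with columns `subject`, `region` (one of
#'   `infarct_core`, `hypoperfused`, `normal_contra`), `voxel` (linear
#'   index), `fa`, `adc`, `tmax`; attribute `dropped` counts removed rows.
#' @export
extractValues <- function(masks, faMap, adcMap, tmaxMap, subject = 1L) {
  fa <- if (is(faMap, "ScalarMap")) mapData(faMap) else faMap
  adc <- if (is(adcMap, "ScalarMap")) mapData(adcMap) else adcMap
  tm <- if (is(tmaxMap, "ScalarMap")) mapData(tmaxMap) else tmaxMap
  regions <- c("infarct_core", "hypoperfused", "normal_contra")
  rows <- lapply(regions, function(rg) {
    idx <- which(regionMask(masks, rg))
    if (!length(idx)) return(NULL)
    data.frame(subject = subject, region = rg, voxel = idx,
               fa = fa[idx], adc = adc[idx], tmax = tm[idx])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = integer(), region = character(),
                      voxel = integer(), fa = numeric(), adc = numeric(),
                      tmax = numeric())
  keep <- is.finite(out$fa) & is.finite(out$adc) & is.finite(out$tmax)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Lesion volume in millilitres
#'
#' @param mask logical array.
#' @param voxelSize voxel dimensions in mm.
#' @return Volume in mL (voxel count times voxel volume).
#' @export
maskVolume <- function(mask, voxelSize) {
  sum(mask) * prod(voxelSize) / 1000
}
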