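#' Read a NIfTI volume
#'
#' Thin wrapper around RNifti: returns the voxel array and its voxel
#' dimensions, optionally checking the dimensionality.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param ndim expected number of dimensions (3 or 4), or `NULL` to accept any.
#' @return list with `data` (array) and `voxelSize` (mm per axis, first 3 axes).
#' @export
readVolume <- function(path, ndim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  data <- as.array(img)
  if (!is.null(ndim) && length(dim(data)) != ndim)
    stop(path, " has ", length(dim(data)), " dimensions; expected ", ndim)
  vox <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(data))))]
  list(data = data, voxelSize = as.numeric(vox))
}

#' Write a NIfTI volume
#'
#' @param data 3-D or 4-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize voxel dimensions in mm (length 3).
#' @return The path, invisibly.
#' @export
writeVolume <- function(data, path, voxelSize = c(1.5, 1.5, 3)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxelSize, rep(1, length(dim(data)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an FSL-style gradient table
#'
#' Parses whitespace-separated `.bval` (one row of b-values) and `.bvec`
#' (three rows: x, y, z components) files. b-values below 50 s/mm^2 are
#' treated as b = 0; non-unit diffusion directions are normalized with a
#' warning.
#'
#' @param bvalPath,bvecPath file paths.
#' @param dscTR,dscTE,dscNTimepoints DSC parameters to carry in the scheme.
#' @return An [AcquisitionScheme-class] preserving the file's volume order.
#' @export
readGradients <- function(bvalPath, bvecPath, dscTR = 1.45, dscTE = 0.022,
                          dscNTimepoints = 60L) {
  bval <- scan(bvalPath, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvecPath))
  if (nrow(bvec) != 3L)
    stop("bvec file must have 3 rows (x, y, z); got ", nrow(bvec))
  if (ncol(bvec) != length(bval))
    stop("bval/bvec count mismatch: ", length(bval), " b-values vs ",
         ncol(bvec), " vectors")
  bval[bval < 50] <- 0
  gx <- bvec[1, ]; gy <- bvec[2, ]; gz <- bvec[3, ]
  dw <- bval > 0
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  if (any(dw & nrm == 0))
    stop("zero gradient vector on a diffusion-weighted volume")
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit gradient directions normalized")
  }
  gx[dw] <- gx[dw] / nrm[dw]; gy[dw] <- gy[dw] / nrm[dw]
  gz[dw] <- gz[dw] / nrm[dw]
  gx[!dw] <- 0; gy[!dw] <- 0; gz[!dw] <- 0
  gt <- data.frame(bval = bval, gx = gx, gy = gy, gz = gz)
  new("AcquisitionScheme", gradientTable = gt, dscTR = dscTR, dscTE = dscTE,
      dscNTimepoints = as.integer(dscNTimepoints))
}

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis with their defaults: the
#' segmentation thresholds (FA > 0.15 white-matter mask, ADC < 600e-6
#' mm^2/s infarct core, 2-SD automatic perfusion ROI), the deconvolution
#' settings (10% singular-value truncation, grid Tmax without sub-sample
#' interpolation), the statistics settings, and the planted cohort
#' calibration used by the phantom (region parameters, the 5.4-s Tmax
#' changepoint with subgroup FA levels 0.390 / 0.423 +/- 0.014, and the
#' hypoperfused Tmax-FA Spearman association 0.561).
#'
#' @return Nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    thresholds = list(faWm = 0.15, adcCore = 600e-6, tmaxRoiK = 2.0),
    deconvolution = list(thresholdFrac = 0.10, interpolateTmax = FALSE),
    statistics = list(splitUnit = "person", minGroupSize = 2L,
                      nPermutations = 10000L, alpha = 0.05),
    segmentation = list(coreWithinRoi = TRUE),
    split = list(changepoint = 5.4, faLow = 0.390, faHigh = 0.423,
                 faSubgroupSD = 0.014, tmaxRange = c(2, 9)),
    association = list(rhoTmaxFaHypoperfused = 0.561),
    seed = 1L
  )
}

validateConfig <- function(cfg) {
  ref <- defaultPipelineConfig()
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  for (grp in intersect(names(cfg), setdiff(names(ref), "seed"))) {
    bad <- setdiff(names(cfg[[grp]]), names(ref[[grp]]))
    if (length(bad)) stop("unknown configuration keys in '", grp, "': ",
                          paste(bad, collapse = ", "))
  }
  out <- utils::modifyList(ref, cfg)
  th <- out$thresholds
  if (th$faWm <= 0 || th$faWm >= 1) stop("thresholds$faWm must lie in (0, 1)")
  if (th$adcCore <= 0) stop("thresholds$adcCore must be positive")
  if (th$tmaxRoiK <= 0) stop("thresholds$tmaxRoiK must be positive")
  de <- out$deconvolution
  if (de$thresholdFrac <= 0 || de$thresholdFrac >= 1)
    stop("deconvolution$thresholdFrac must lie strictly between 0 and 1")
  st <- out$statistics
  if (!st$splitUnit %in% c("person", "voxel"))
    stop("statistics$splitUnit must be 'person' or 'voxel'")
  if (st$minGroupSize < 1) stop("statistics$minGroupSize must be >= 1")
  if (st$nPermutations < 0) stop("statistics$nPermutations must be >= 0")
  if (st$alpha <= 0 || st$alpha >= 1) stop("statistics$alpha must lie in (0, 1)")
  out$statistics$minGroupSize <- as.integer(st$minGroupSize)
  out$statistics$nPermutations <- as.integer(st$nPermutations)
  out$seed <- as.integer(out$seed)
  out
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration, rejects unknown keys, range-checks every
#' value, and fills unset entries from [defaultPipelineConfig()].
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  if (is.null(path)) return(defaultPipelineConfig())
  validateConfig(yaml::read_yaml(path))
}

configHash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
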