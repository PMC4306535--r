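#' Convert a DSC signal series to tracer concentration
#'
#' Applies the standard gradient-echo relation
#' \eqn{C(t) = -\ln(S(t)/S_0)/TE}, with the baseline \eqn{S_0} taken as the
#' mean of the first `baselineN` pre-bolus timepoints. Nonpositive signal
#' samples (possible at high noise) are clipped to a small positive floor
#' before the logarithm and counted in the `"clipped"` attribute. Voxels
#' whose signal is identically zero are excluded (all-`NA` concentration).
#'
#' @param signal numeric vector (one voxel) or matrix with time in rows and
#'   voxels in columns.
#' @param te echo time in seconds.
#' @param baselineN number of pre-bolus baseline timepoints (>= 3).
#' @return Concentration in the same shape as `signal` (units 1/s), with an
#'   attribute `clipped` giving the number of floored samples.
#' @export
signalToConcentration <- function(signal, te, baselineN = 8L) {
  if (baselineN < 3L) stop("baselineN must be >= 3")
  vec <- is.null(dim(signal))
  s <- if (vec) matrix(signal, ncol = 1L) else signal
  if (nrow(s) <= baselineN) stop("signal shorter than the baseline window")
  s0 <- colMeans(s[seq_len(baselineN), , drop = FALSE])
  dead <- !(s0 > 0) | colSums(abs(s)) == 0
  floorv <- pmax(s0 * 1e-6, .Machine$double.xmin)
  clipped <- sum(sweep(s, 2, floorv, `<`)[, !dead, drop = FALSE])
  s <- pmax(s, rep(floorv, each = nrow(s)))
  conc <- -log(sweep(s, 2, s0, `/`)) / te
  conc[, dead] <- NA_real_
  if (vec) conc <- conc[, 1L]
  attr(conc, "clipped") <- clipped
  conc
}

#' Truncated-SVD inverse of the block-circulant AIF matrix
#'
#' Builds the circulant convolution matrix of the arterial input function at
#' zero-padded length 2N (so linear convolution of length-N curves is
#' represented without time aliasing) and returns its regularized
#' pseudo-inverse, discarding singular values below `thresholdFrac` times
#' the largest. The circulant construction makes the deconvolution
#' insensitive to bolus arrival delay: circularly shifting the tissue curve
#' circularly shifts the recovered residue.
#'
#' @param aif arterial concentration curve, length N.
#' @param tr sampling interval (s).
#' @param thresholdFrac truncation threshold as a fraction of the largest
#'   singular value, in (0, 1). Default 0.10.
#' @return A 2N x 2N matrix mapping a zero-padded tissue curve to the
#'   flow-scaled residue function.
#' @export
blockCirculantPinv <- function(aif, tr, thresholdFrac = 0.10) {
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    stop("thresholdFrac must lie strictly between 0 and 1")
  if (all(aif == 0)) stop("AIF is identically zero")
  A <- circulantAifMatrix(aif, tr)
  sv <- svd(A)
  keep <- sv$d >= thresholdFrac * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

# The block-circulant convolution operator itself (2N x 2N); shared by the
# deconvolution and by the phantom's grid-mode forward model so that the
# two are exact inverses up to SVD truncation.
circulantAifMatrix <- function(aif, tr) {
  n <- length(aif)
  n2 <- 2L * n
  apad <- c(aif, numeric(n))
  idx <- (outer(seq_len(n2), seq_len(n2), `-`) %% n2) + 1L
  matrix(apad[idx], n2, n2) * tr
}

#' Deconvolve tissue concentration curves against an AIF
#'
#' Block-circulant SVD deconvolution: the tissue curve is zero-padded to
#' length 2N and multiplied by the truncated pseudo-inverse of the circulant
#' AIF matrix, yielding the flow-scaled residue function
#' \eqn{k(t) = CBF \cdot R(t - delay)}. The operation is linear in the
#' tissue curve.
#'
#' @param tissue concentration vector (length N) or matrix (N rows, one
#'   column per voxel).
#' @param aif arterial concentration curve of the same length N.
#' @param tr sampling interval (s).
#' @param thresholdFrac singular-value truncation fraction; see
#'   [blockCirculantPinv()].
#' @param pinv optionally, a precomputed result of [blockCirculantPinv()]
#'   (reused across voxels for speed).
#' @return Residue curve(s) of length 2N (same column layout as `tissue`).
#'   The Tmax search uses only the first N samples.
#' @export
deconvolveOsvd <- function(tissue, aif, tr, thresholdFrac = 0.10, pinv = NULL) {
  vec <- is.null(dim(tissue))
  ct <- if (vec) matrix(tissue, ncol = 1L) else tissue
  if (nrow(ct) != length(aif))
    stop("tissue and AIF curves must have equal length")
  if (is.null(pinv)) pinv <- blockCirculantPinv(aif, tr, thresholdFrac)
  k <- pinv %*% rbind(ct, matrix(0, nrow(ct), ncol(ct)))
  if (vec) k[, 1L] else k
}

# Peak location of residue curves: argmax over the first nTime samples, in
# seconds, with optional parabolic sub-sample refinement around the peak.
# Columns that are all-NA or identically zero give NaN.
tmaxFromResidue <- function(k, tr, nTime, interpolate = FALSE) {
  kk <- if (is.null(dim(k))) matrix(k, ncol = 1L) else k
  kk <- kk[seq_len(nTime), , drop = FALSE]
  out <- rep(NaN, ncol(kk))
  for (j in seq_len(ncol(kk))) {
    y <- kk[, j]
    if (!any(is.finite(y)) || all(y == 0, na.rm = TRUE)) next
    i <- which.max(y)
    t0 <- (i - 1) * tr
    if (interpolate && i > 1L && i < nTime) {
      den <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (is.finite(den) && den < 0) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / den
        t0 <- t0 + max(min(delta, 0.5), -0.5) * tr
      }
    }
    out[j] <- max(t0, 0)
  }
  out
}

#' Tmax map from deconvolved residue functions
#'
#' Tmax is the time-to-maximum of the residue function: the argmax index
#' times the repetition time, searched over the first N (unpadded) samples.
#' With `interpolate = TRUE` a parabola through the peak sample and its two
#' neighbours refines the estimate below the TR grid; the default reports
#' on the acquisition grid.
#'
#' @param residues matrix of residue curves (2N rows from
#'   [deconvolveOsvd()], one column per voxel in grid order).
#' @param mask logical 3-D array selecting the voxels the columns refer to.
#' @param tr sampling interval (s).
#' @param nTime number of acquired timepoints N.
#' @param interpolate logical; parabolic sub-sample interpolation (default
#'   `FALSE`).
#' @param voxelSize voxel dimensions (mm) for the output map.
#' @return A [ScalarMap-class] of kind `"Tmax"`; `NA` outside the mask,
#'   `NaN` where the residue was degenerate (all zero).
#' @export
tmaxMap <- function(residues, mask, tr, nTime, interpolate = FALSE,
                    voxelSize = c(1.5, 1.5, 3)) {
  vals <- tmaxFromResidue(residues, tr, nTime, interpolate)
  if (sum(mask) != length(vals))
    stop("number of residue columns does not match the mask")
  out <- array(NA_real_, dim(mask))
  out[mask] <- vals
  ScalarMap(out, voxelSize, "Tmax")
}
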