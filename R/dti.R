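#' Fractional anisotropy from tensor eigenvalues
#'
#' Computes the standard FA,
#' \deqn{FA = \sqrt{3/2}\;\frac{\sqrt{\sum_i(\lambda_i-\bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},}
#' after clamping negative eigenvalues to zero, so the result always lies in
#' \[0, 1\]. The zero tensor is assigned FA = 0 by convention.
#'
#' @param l1,l2,l3 eigenvalue vectors (mm^2/s); recycled to a common length.
#' @return Numeric vector of FA values in \[0, 1\].
#' @examples
#' faFromEigenvalues(1.7e-3, 0.3e-3, 0.3e-3)
#' faFromEigenvalues(1e-3, 1e-3, 1e-3)   # isotropic: 0
#' @export
faFromEigenvalues <- function(l1, l2, l3) {
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Apparent diffusion coefficient (mean diffusivity) from eigenvalues
#'
#' @inheritParams faFromEigenvalues
#' @return `(l1 + l2 + l3) / 3` after clamping negatives to zero, in mm^2/s.
#' @export
adcFromEigenvalues <- function(l1, l2, l3) {
  (pmax(l1, 0) + pmax(l2, 0) + pmax(l3, 0)) / 3
}

# Design matrix of the log-linear tensor model: one row per volume,
# columns (1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz).
tensorDesign <- function(scheme) {
  gt <- gradientTable(scheme)
  b <- gt$bval
  cbind(
    1,
    -b * gt$gx^2, -b * gt$gy^2, -b * gt$gz^2,
    -2 * b * gt$gx * gt$gy, -2 * b * gt$gx * gt$gz, -2 * b * gt$gy * gt$gz
  )
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves, per voxel, the linearized Stejskal-Tanner model
#' \eqn{\ln S_i = \ln S_0 - b\, g_i^\top D\, g_i} by ordinary least squares
#' on the log-signals. Because the b = 0 volumes enter the log-domain fit,
#' the implied baseline estimate is their geometric mean. The fit is exact
#' on noiseless data.
#'
#' Voxels containing any nonpositive signal inside the mask are flagged and
#' excluded (their outputs are `NA`), since the log-model is undefined there.
#'
#' @param dwi 4-D numeric array (x, y, z, volume), volumes ordered as in the
#'   scheme's gradient table.
#' @param scheme an [AcquisitionScheme-class].
#' @param mask optional logical 3-D array restricting the fit; default all voxels.
#' @return A list with `tensor` (4-D array, sixth-dimension components Dxx,
#'   Dyy, Dzz, Dxy, Dxz, Dyz), `s0` (3-D array), and `excluded` (logical 3-D
#'   array of masked-in voxels that had nonpositive signals).
#' @export
fitTensor <- function(dwi, scheme, mask = NULL) {
  dims <- dim(dwi)
  if (length(dims) != 4L) stop("dwi must be a 4-D array (x, y, z, volume)")
  gt <- gradientTable(scheme)
  if (dims[4] != nrow(gt))
    stop("number of volumes (", dims[4], ") does not match the gradient table (",
         nrow(gt), " rows)")
  if (sum(gt$bval > 0) < 6L)
    stop("tensor fit needs at least 6 diffusion-weighted directions")
  X <- tensorDesign(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("gradient directions are collinear: tensor design matrix is rank deficient")
  pinv <- solve(crossprod(X), t(X))   # 7 x nvol

  nvox <- prod(dims[1:3])
  sig <- matrix(dwi, nvox, dims[4])
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!identical(dim(mask), as.integer(dims[1:3])) &&
      !identical(dim(mask), dims[1:3]))
    stop("mask grid does not match the DWI grid")
  inMask <- as.logical(mask)

  bad <- inMask & (rowSums(sig <= 0 | !is.finite(sig)) > 0L)
  use <- inMask & !bad

  coef <- matrix(NA_real_, nvox, 7)
  if (any(use))
    coef[use, ] <- log(sig[use, , drop = FALSE]) %*% t(pinv)

  tensor <- array(coef[, 2:7], c(dims[1:3], 6))
  dimnames(tensor) <- c(rep(list(NULL), 3),
                        list(c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")))
  list(
    tensor = tensor,
    s0 = array(exp(coef[, 1]), dims[1:3]),
    excluded = array(bad, dims[1:3])
  )
}

#' Compute FA and ADC maps from a DWI series
#'
#' Convenience composition of [fitTensor()], a closed-form symmetric 3x3
#' eigen-decomposition (eigenvalues in descending order), clamping of
#' negative eigenvalues to zero, and [faFromEigenvalues()] /
#' [adcFromEigenvalues()].
#'
#' @inheritParams fitTensor
#' @param voxelSize voxel dimensions in mm for the output maps.
#' @return A list with elements `fa` and `adc`, both [ScalarMap-class]
#'   objects (`NA` outside the mask and at excluded voxels), plus
#'   `eigenvalues` (nvox x 3 matrix) for downstream use.
#' @export
computeMaps <- function(dwi, scheme, mask = NULL, voxelSize = c(1.5, 1.5, 3)) {
  fit <- fitTensor(dwi, scheme, mask)
  dims <- dim(fit$s0)
  tv <- matrix(fit$tensor, prod(dims), 6)
  ev <- eigSym3(tv[, 1], tv[, 2], tv[, 3], tv[, 4], tv[, 5], tv[, 6])
  ev <- pmax(ev, 0)
  fa <- faFromEigenvalues(ev[, 1], ev[, 2], ev[, 3])
  adc <- adcFromEigenvalues(ev[, 1], ev[, 2], ev[, 3])
  ok <- is.finite(tv[, 1])
  fa[!ok] <- NA_real_
  adc[!ok] <- NA_real_
  list(
    fa = ScalarMap(array(fa, dims), voxelSize, "FA"),
    adc = ScalarMap(array(adc, dims), voxelSize, "ADC"),
    eigenvalues = ev
  )
}
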