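#' Eigenvalue triple for a target FA and mean diffusivity
#'
#' Inverts the FA definition under an axially symmetric tensor model
#' (\eqn{\lambda_2 = \lambda_3}): returns the unique eigenvalue triple with
#' mean `md` and fractional anisotropy `fa`, with
#' \eqn{\lambda_1 = md(1 + 2\alpha)}, \eqn{\lambda_{2,3} = md(1 - \alpha)}
#' and \eqn{\alpha = \sqrt{3 fa^2 / (9 - 6 fa^2)}}.
#'
#' @param fa target fractional anisotropy, `0 <= fa < 1` (vectorized).
#' @param md target mean diffusivity in mm^2/s, `md > 0` (vectorized).
#' @return An n x 3 matrix of eigenvalues (columns l1 >= l2 = l3 >= 0).
#' @examples
#' ev <- solveEigenvalues(0.397, 0.75e-3)
#' faFromEigenvalues(ev[, 1], ev[, 2], ev[, 3])   # 0.397
#' @export
solveEigenvalues <- function(fa, md) {
  n <- max(length(fa), length(md))
  fa <- rep_len(fa, n); md <- rep_len(md, n)
  if (any(fa < 0 | fa >= 1)) stop("fa must satisfy 0 <= fa < 1")
  if (any(md <= 0)) stop("md must be positive")
  alpha <- sqrt(3 * fa^2 / (9 - 6 * fa^2))
  l2 <- md * (1 - alpha)
  if (any(l2 < 0)) stop("fa/md combination yields a negative eigenvalue")
  cbind(l1 = md * (1 + 2 * alpha), l2 = l2, l3 = l2)
}

# Deterministic near-uniform gradient set: spherical Fibonacci points on the
# upper hemisphere. Antipodal symmetry of diffusion measurements makes a
# hemisphere sufficient.
fibonacciDirections <- function(n = 20L) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default acquisition scheme
#'
#' One b = 0 volume plus 20 noncollinear directions at b = 1000 s/mm^2, and
#' a 60-timepoint DSC series at TR 1.45 s / TE 22 ms.
#'
#' @param nDirections number of diffusion directions.
#' @return An [AcquisitionScheme-class].
#' @export
defaultScheme <- function(nDirections = 20L) {
  AcquisitionScheme(fibonacciDirections(nDirections), bValue = 1000, nB0 = 1L,
                    dscTR = 1.45, dscTE = 0.022, dscNTimepoints = 60L)
}

#' Default tissue-compartment parameters
#'
#' Between-subject means and SDs of FA, mean diffusivity and Tmax for the
#' four compartments. FA values are the cohort means/SDs for normal
#' (0.360 +/- 0.020), hypoperfused (0.397 +/- 0.019) and infarcted
#' (0.313 +/- 0.037) white matter. ADC and Tmax parameters are realistic
#' calibrations: normal and hypoperfused WM share the same diffusivity
#' (their ADC contrast is null), the infarct-core diffusivity distribution
#' is truncated below the defining 600e-6 mm^2/s threshold, and Tmax is
#' elevated in the hypoperfused (6.5 s) and infarcted (8.0 s) compartments.
#' Gray matter gets low FA (0.10) so the FA > 0.15 mask excludes it.
#'
#' @return data.frame with one row per compartment.
#' @export
defaultRegionParams <- function() {
  data.frame(
    label = c("normal_wm", "gray_matter", "hypoperfused_wm", "infarct_core"),
    faMean = c(0.360, 0.100, 0.397, 0.313),
    faSD = c(0.020, 0.020, 0.019, 0.037),
    mdMean = c(0.72e-3, 0.85e-3, 0.72e-3, 0.50e-3),
    mdSD = c(0.03e-3, 0.04e-3, 0.03e-3, 0.05e-3),
    mdUpper = c(Inf, Inf, Inf, 600e-6),
    tmaxMean = c(0.8, 0.8, 6.5, 8.0),
    tmaxSD = c(0.3, 0.3, 1.5, 2.0),
    s0 = c(100, 100, 100, 100)
  )
}

defaultDscModel <- function() {
  list(
    aifOnset = 13.05,     # s; leaves >= 9 pre-bolus samples at TR 1.45 s
    aifShape = 3,         # gamma-variate shape
    aifScale = 0.8,       # s; compact first-pass bolus at a 5 mL/s injection
    aifAmplitude = 700,   # peak arterial Delta-R2* (1/s)
    mtt = 4,              # tissue mean transit time (s)
    cbf = 0.012,          # flow scale (1/s)
    baselineN = 8L,
    thresholdFrac = 0.10
  )
}

#' Default phantom specification
#'
#' A 32 x 32 x 8 grid (1.5 x 1.5 x 3 mm voxels) with a lateralized lesion:
#' a rectangular perfusion lesion in one hemisphere containing an inner
#' infarct core, a mirror-image contralateral normal-WM region, gray-matter
#' slabs at the grid edges, and normal WM elsewhere.
#'
#' @param nSubjects cohort size (default 21).
#' @param gridShape grid dimensions.
#' @param snrDwi baseline DWI signal-to-noise ratio (Rician); `Inf` disables noise.
#' @param dscNoiseSD Gaussian DSC signal noise SD (baseline signal is 100).
#' @param seed base cohort seed.
#' @param regions compartment parameter table, see [defaultRegionParams()].
#' @param voxelSD within-region voxel-level SDs (named `fa`, `md`, `tmax`).
#' @param tmaxConvention `"grid"` or `"interpolated"`; see
#'   [PhantomSpec-class].
#' @return A [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function(nSubjects = 21L, gridShape = c(32L, 32L, 8L),
                               snrDwi = 30, dscNoiseSD = 1.5, seed = 1L,
                               regions = defaultRegionParams(),
                               voxelSD = c(fa = 0.010, md = 0.02e-3, tmax = 0.5),
                               tmaxConvention = "grid") {
  new("PhantomSpec",
    gridShape = as.integer(gridShape), voxelSize = c(1.5, 1.5, 3),
    regions = regions, snrDwi = snrDwi, dscNoiseSD = dscNoiseSD,
    nSubjects = as.integer(nSubjects), seed = as.integer(seed),
    voxelSD = voxelSD, dscModel = defaultDscModel(),
    tmaxConvention = tmaxConvention)
}

# Region geometry on an arbitrary grid: block lesion in the x-high
# hemisphere, inner core, mirrored contralateral ROI, GM slabs at the y
# edges. Returns the label map plus the two ROI masks.
regionGeometry <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  lab <- array(1L, gridShape)                     # normal WM
  gmW <- max(1L, round(ny / 16))
  lab[, c(seq_len(gmW), seq(ny - gmW + 1L, ny)), ] <- 2L

  lx <- seq(round(nx * 0.625), round(nx * 0.90625))
  ly <- seq(round(ny * 0.34375), round(ny * 0.6875))
  lz <- seq(max(1, round(nz * 0.375)), round(nz * 0.75))
  cx <- seq(round(nx * 0.6875), round(nx * 0.84375))
  cy <- seq(round(ny * 0.4375), round(ny * 0.59375))
  cz <- seq(max(1, round(nz * 0.5)), round(nz * 0.625))

  perfusionRoi <- array(FALSE, gridShape)
  perfusionRoi[lx, ly, lz] <- TRUE
  lab[lx, ly, lz] <- 3L                            # hypoperfused
  lab[cx, cy, cz] <- 4L                            # infarct core

  contraRoi <- array(FALSE, gridShape)
  contraRoi[nx + 1L - lx, ly, lz] <- TRUE
  if (any(contraRoi & perfusionRoi))
    stop("grid too small: mirrored contralateral ROI overlaps the lesion")
  list(labelMap = lab, perfusionRoi = perfusionRoi, contraRoi = contraRoi)
}

#' Lesion and contralateral ROI masks implied by a phantom specification
#'
#' @param spec a [PhantomSpec-class].
#' @return list with logical arrays `perfusionRoi` (the planted perfusion
#'   lesion, core included), `contraRoi` (its mirror image in the opposite
#'   hemisphere) and `brain` (all voxels).
#' @export
phantomRois <- function(spec) {
  g <- regionGeometry(spec@gridShape)
  list(perfusionRoi = g$perfusionRoi, contraRoi = g$contraRoi,
       brain = array(TRUE, spec@gridShape))
}

#' Draw one subject's ground truth
#'
#' Subject-level regional values are drawn from truncated normal
#' distributions (FA truncated to \[0.01, 0.95\], diffusivity to positive
#' values and below any `mdUpper` bound, Tmax to nonnegative values); voxel
#' values add within-region jitter of SD `voxelSD` around the subject's
#' regional value.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for this subject.
#' @return A [GroundTruth-class].
#' @export
makeGroundTruth <- function(spec, seed) {
  set.seed(seed)
  geo <- regionGeometry(spec@gridShape)
  lab <- geo$labelMap
  r <- spec@regions
  vsd <- spec@voxelSD
  fa <- array(NA_real_, spec@gridShape)
  md <- array(NA_real_, spec@gridShape)
  tm <- array(NA_real_, spec@gridShape)
  draws <- data.frame(region = r$label, fa = NA_real_, md = NA_real_,
                      tmax = NA_real_)
  mdUp <- if ("mdUpper" %in% names(r)) r$mdUpper else rep(Inf, nrow(r))
  for (i in seq_len(nrow(r))) {
    idx <- which(lab == match(r$label[i],
                              c("normal_wm", "gray_matter",
                                "hypoperfused_wm", "infarct_core")))
    if (!length(idx)) stop("region ", r$label[i], " has no voxels on this grid")
    sFa <- rtruncNorm(1, r$faMean[i], r$faSD[i], 0, 0.95)
    sMd <- rtruncNorm(1, r$mdMean[i], r$mdSD[i], 1e-4, mdUp[i])
    sTm <- rtruncNorm(1, r$tmaxMean[i], r$tmaxSD[i], 0)
    draws$fa[i] <- sFa; draws$md[i] <- sMd; draws$tmax[i] <- sTm
    nv <- length(idx)
    fa[idx] <- rtruncNorm(nv, sFa, vsd["fa"], 0, 0.95)
    md[idx] <- rtruncNorm(nv, sMd, vsd["md"], 1e-4)
    tm[idx] <- rtruncNorm(nv, sTm, vsd["tmax"], 0)
  }
  new("GroundTruth", labelMap = lab, trueFa = fa, trueAdc = md, trueTmax = tm,
      subjectRegions = draws)
}

# Fixed principal diffusion direction per region label.
regionPrincipalDirections <- function() {
  rbind(
    c(1, 0, 0),                 # normal WM
    c(0, 1, 0),                 # gray matter
    c(0, 0, 1),                 # hypoperfused WM
    c(1, 1, 1) / sqrt(3)        # infarct core
  )
}

#' Simulate a DWI series from planted ground truth
#'
#' Per voxel, the signal for direction \eqn{g_i} is
#' \eqn{S_i = S_0 \exp(-b\, g_i^\top D\, g_i)} with an axially symmetric
#' tensor built from [solveEigenvalues()] and a fixed per-region principal
#' direction; Rician noise with SD \eqn{\bar S_0 / snr} corrupts the
#' magnitudes. Deterministic given `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param scheme an [AcquisitionScheme-class].
#' @param truth a [GroundTruth-class] on the spec's grid.
#' @param seed integer noise seed.
#' @return 4-D array (x, y, z, volume) matching the scheme's gradient table.
#' @export
simulateDwi <- function(spec, scheme, truth, seed = spec@seed) {
  if (!identical(dim(truth@labelMap), spec@gridShape))
    stop("ground truth is not on the spec's grid")
  set.seed(seed)
  gt <- gradientTable(scheme)
  nvol <- nrow(gt)
  nvox <- prod(spec@gridShape)
  dirs <- as.matrix(gt[, c("gx", "gy", "gz")])
  b <- gt$bval
  pdir <- regionPrincipalDirections()
  sig <- matrix(0, nvox, nvol)
  s0map <- numeric(nvox)
  lab <- as.integer(truth@labelMap)
  for (reg in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == reg)
    ev <- solveEigenvalues(truth@trueFa[idx], truth@trueAdc[idx])
    proj2 <- as.numeric(dirs %*% pdir[reg, ])^2          # per volume
    # exponent_{voxel, volume} = b_j * (l2_i + (l1_i - l2_i) * proj2_j)
    expo <- outer(ev[, 2], b) + outer(ev[, 1] - ev[, 2], b * proj2)
    s0 <- spec@regions$s0[match(
      c("normal_wm", "gray_matter", "hypoperfused_wm", "infarct_core")[reg],
      spec@regions$label)]
    sig[idx, ] <- s0 * exp(-expo)
    s0map[idx] <- s0
  }
  if (is.finite(spec@snrDwi)) {
    sd <- mean(s0map[lab > 0]) / spec@snrDwi
    sig[lab > 0, ] <- addRicianNoise(sig[lab > 0, ], sd)
  }
  array(sig, c(spec@gridShape, nvol))
}

#' Gamma-variate arterial input function
#'
#' \eqn{C_a(t) = A\,(\tau/(\alpha\beta))^{\alpha} e^{\alpha - \tau/\beta}}
#' for \eqn{\tau = t - t_0 > 0} (zero before onset), peaking at
#' \eqn{t_0 + \alpha\beta} with peak value A.
#'
#' @param times sample times in seconds.
#' @param onset bolus arrival time \eqn{t_0} (s).
#' @param shape,scale gamma-variate shape \eqn{\alpha} and scale \eqn{\beta} (s).
#' @param amplitude peak concentration A (1/s).
#' @return Concentration samples.
#' @export
gammaVariateAif <- function(times, onset = 13.05, shape = 3, scale = 0.8,
                            amplitude = 700) {
  tau <- times - onset
  out <- numeric(length(times))
  pos <- tau > 0
  out[pos] <- amplitude * (tau[pos] / (shape * scale))^shape *
    exp(shape - tau[pos] / scale)
  out
}

# Residue-function samples for a set of arrival delays: columns are voxels,
# rows the N sample times; exponential residue exp(-(t - d)/mtt), zero
# before arrival.
residueSamples <- function(delays, tr, nTime, mtt) {
  t <- (seq_len(nTime) - 1) * tr
  r <- exp(-outer(t, delays, `-`) / mtt)
  r[outer(t, delays, `<`)] <- 0
  r
}

# Continuous-time tissue concentration model, tabulated against arrival
# delay. The convolution CBF * (AIF conv R)(t) is evaluated on a fine
# internal time grid (tr / fineFactor) by FFT and sampled at the
# acquisition times, for a lookup grid of delays; simulateDsc then
# interpolates between lookup columns. A coarse (acquisition-grid)
# convolution would lose all sub-sample delay information: sampling the
# delayed exponential residue on the TR grid only rescales it within a
# grid cell.
dscConcLookup <- function(scheme, dscModel, maxDelay = 14, dStep = 0.05,
                          fineFactor = 16L) {
  tr <- dscTR(scheme)
  n <- dscTimepoints(scheme)
  dt <- tr / fineFactor
  tf <- seq(0, (n - 1) * tr, by = dt)
  nf <- length(tf)
  af <- gammaVariateAif(tf, dscModel$aifOnset, dscModel$aifShape,
                        dscModel$aifScale, dscModel$aifAmplitude)
  d <- seq(0, maxDelay, by = dStep)
  rf <- exp(-outer(tf, d, `-`) / dscModel$mtt)
  rf[outer(tf, d, `<`)] <- 0
  npad <- stats::nextn(2L * nf)
  fa <- stats::fft(c(af, numeric(npad - nf)))
  fr <- stats::mvfft(rbind(rf, matrix(0, npad - nf, length(d))))
  cf <- Re(stats::mvfft(fa * fr, inverse = TRUE))[seq_len(nf), , drop = FALSE] /
    npad * dt
  conc <- dscModel$cbf * cf[seq(1L, nf, by = fineFactor), , drop = FALSE]
  list(delay = d, conc = conc, tr = tr, n = n)
}

# Tissue concentration curves for arbitrary delays, by linear interpolation
# between lookup columns (the curve is smooth in the delay).
concForDelays <- function(lookup, delays) {
  if (any(delays < 0) || any(delays > max(lookup$delay)))
    stop("delay outside the tabulated range")
  step <- lookup$delay[2] - lookup$delay[1]
  pos <- delays / step
  k <- pmin(floor(pos), length(lookup$delay) - 2L)
  w <- pos - k
  lookup$conc[, k + 1L, drop = FALSE] * rep(1 - w, each = lookup$n) +
    lookup$conc[, k + 2L, drop = FALSE] * rep(w, each = lookup$n)
}

#' Calibration curve of recovered versus planted Tmax delay
#'
#' Forward-simulates a noiseless tissue curve for a sweep of arrival
#' delays, deconvolves it with [deconvolveOsvd()], and records the
#' parabolic-interpolated Tmax. The monotonized recovery curve is returned
#' together with its inverse, which the phantom uses (under the
#' `"interpolated"` convention) to choose arrival delays so that the
#' deconvolved residue's interpolated argmax equals the planted Tmax.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param dscModel DSC model constants (see [PhantomSpec-class]); defaults
#'   to the package's standard model.
#' @param maxDelay largest delay in the sweep (s).
#' @param step sweep resolution (s).
#' @return list with `delay`, `recovered` (monotonized), and `inverse`, a
#'   function mapping a target Tmax to the delay that produces it.
#' @export
tmaxCalibration <- function(scheme, dscModel = defaultDscModel(),
                            maxDelay = 14, step = 0.05, lookup = NULL) {
  tr <- dscTR(scheme)
  n <- dscTimepoints(scheme)
  t <- (seq_len(n) - 1) * tr
  aif <- gammaVariateAif(t, dscModel$aifOnset, dscModel$aifShape,
                         dscModel$aifScale, dscModel$aifAmplitude)
  pinv <- blockCirculantPinv(aif, tr, dscModel$thresholdFrac)
  if (is.null(lookup))
    lookup <- dscConcLookup(scheme, dscModel, maxDelay, step)
  d <- lookup$delay
  k <- pinv %*% rbind(lookup$conc, matrix(0, n, length(d)))
  rec <- tmaxFromResidue(k, tr, n, interpolate = TRUE)
  mono <- stats::isoreg(d, rec)$yf
  inv <- function(target) {
    stats::approx(x = mono, y = d, xout = target, ties = "ordered",
                  rule = 2)$y
  }
  list(delay = d, recovered = mono, inverse = inv, lookup = lookup)
}

#' Simulate a DSC perfusion series from planted ground truth
#'
#' The arterial input is a gamma-variate curve; the tissue concentration is
#' the continuous-time convolution
#' \eqn{C(t) = CBF \cdot (C_a \ast R)(t)} (evaluated on a fine internal
#' time grid and sampled at the acquisition times) with exponential residue
#' \eqn{R(t) = e^{-t/MTT}} delayed by each voxel's arrival delay; the signal
#' is \eqn{S(t) = S_0 e^{-TE\, C(t)}} with additive Gaussian noise. At least
#' 8 pre-bolus baseline timepoints precede the bolus. Under the `"grid"`
#' convention the delay equals the planted Tmax; under `"interpolated"` it
#' is chosen with [tmaxCalibration()] so the deconvolved, interpolated
#' argmax equals the planted Tmax. Deterministic given `seed`.
#'
#' @inheritParams simulateDwi
#' @return list with `dsc` (4-D array x, y, z, time), `aif` (arterial
#'   concentration samples), and `times` (s).
#' @export
simulateDsc <- function(spec, scheme, truth, seed = spec@seed) {
  if (!identical(dim(truth@labelMap), spec@gridShape))
    stop("ground truth is not on the spec's grid")
  set.seed(seed)
  dm <- spec@dscModel
  tr <- dscTR(scheme)
  n <- dscTimepoints(scheme)
  t <- (seq_len(n) - 1) * tr
  aif <- gammaVariateAif(t, dm$aifOnset, dm$aifShape, dm$aifScale,
                         dm$aifAmplitude)
  lab <- as.integer(truth@labelMap)
  inb <- lab > 0
  tm <- truth@trueTmax[inb]
  window <- (n - 1) * tr - (dm$aifOnset + dm$aifShape * dm$aifScale)
  if (any(tm > window))
    stop("planted Tmax delay exceeds the acquisition window")
  if (spec@tmaxConvention == "interpolated") {
    lookup <- dscConcLookup(scheme, dm, maxDelay = max(max(tm) + 3, 10))
    cal <- tmaxCalibration(scheme, dm, lookup = lookup)
    conc <- concForDelays(lookup, cal$inverse(tm))
  } else {
    # TR-grid convention: the residue is sampled on the acquisition grid and
    # convolved with the deconvolution's own block-circulant operator, so
    # grid-aligned delays are recovered exactly.
    A <- circulantAifMatrix(aif, tr)
    r <- dm$cbf * residueSamples(tm, tr, n, dm$mtt)
    conc <- (A %*% rbind(r, matrix(0, n, ncol(r))))[seq_len(n), , drop = FALSE]
  }
  s0 <- numeric(sum(inb))
  labNames <- c("normal_wm", "gray_matter", "hypoperfused_wm", "infarct_core")
  for (reg in sort(unique(lab[inb])))
    s0[lab[inb] == reg] <-
      spec@regions$s0[match(labNames[reg], spec@regions$label)]
  sig <- t(conc)                      # voxels x time
  sig <- rep(s0, n) * exp(-dscTE(scheme) * sig)
  dim(sig) <- c(sum(inb), n)
  if (spec@dscNoiseSD > 0)
    sig <- sig + stats::rnorm(length(sig), 0, spec@dscNoiseSD)
  out <- array(0, c(prod(spec@gridShape), n))
  out[inb, ] <- sig
  list(dsc = array(out, c(spec@gridShape, n)), aif = aif, times = t)
}

#' Simulate one subject's full dataset in memory
#'
#' @param spec a [PhantomSpec-class].
#' @param scheme an [AcquisitionScheme-class].
#' @param subject subject index (1-based); seeds are derived from the
#'   spec's base seed and this index.
#' @return list with `truth` ([GroundTruth-class]), `dwi` (4-D array),
#'   `dsc` (list from [simulateDsc()]), and `rois` (from [phantomRois()]).
#' @export
simulateSubject <- function(spec, scheme = defaultScheme(), subject = 1L) {
  truth <- makeGroundTruth(spec, deriveSeed(spec@seed, subject * 3L))
  dwi <- simulateDwi(spec, scheme, truth, deriveSeed(spec@seed, subject * 3L + 1L))
  dsc <- simulateDsc(spec, scheme, truth, deriveSeed(spec@seed, subject * 3L + 2L))
  list(truth = truth, dwi = dwi, dsc = dsc, rois = phantomRois(spec))
}

#' Generate a cohort of phantom datasets on disk
#'
#' Writes, for each subject, the DWI (with FSL-style `.bval`/`.bvec`), the
#' DSC series, the arterial input function, the ROI masks and the ground
#' truth (label map plus true FA/ADC/Tmax volumes), and a cohort-level TSV
#' of the per-subject regional truth draws.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir output directory (created if needed).
#' @param scheme an [AcquisitionScheme-class].
#' @return Invisibly, a list with `subjectDirs` and `truthTable`.
#' @export
generateCohort <- function(spec, outDir, scheme = defaultScheme()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  gt <- gradientTable(scheme)
  truthRows <- list()
  dirs <- character(spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    sd <- file.path(outDir, sprintf("sub-%02d", s))
    dir.create(sd, showWarnings = FALSE)
    bundle <- simulateSubject(spec, scheme, s)
    writeVolume(bundle$dwi, file.path(sd, "dwi.nii.gz"), spec@voxelSize)
    writeLines(paste(gt$bval, collapse = " "), file.path(sd, "dwi.bval"))
    bv <- rbind(gt$gx, gt$gy, gt$gz)
    writeLines(apply(bv, 1, paste, collapse = " "), file.path(sd, "dwi.bvec"))
    writeVolume(bundle$dsc$dsc, file.path(sd, "dsc.nii.gz"), spec@voxelSize)
    writeLines(format(bundle$dsc$aif, digits = 10), file.path(sd, "aif.txt"))
    writeVolume(bundle$rois$perfusionRoi + 0, file.path(sd, "perfusion_roi.nii.gz"),
                spec@voxelSize)
    writeVolume(bundle$rois$contraRoi + 0, file.path(sd, "contra_roi.nii.gz"),
                spec@voxelSize)
    writeVolume(bundle$truth@labelMap, file.path(sd, "labels.nii.gz"),
                spec@voxelSize)
    writeVolume(bundle$truth@trueFa, file.path(sd, "truth_fa.nii.gz"), spec@voxelSize)
    writeVolume(bundle$truth@trueAdc, file.path(sd, "truth_adc.nii.gz"), spec@voxelSize)
    writeVolume(bundle$truth@trueTmax, file.path(sd, "truth_tmax.nii.gz"),
                spec@voxelSize)
    truthRows[[s]] <- cbind(subject = s, bundle$truth@subjectRegions)
    dirs[s] <- sd
  }
  tab <- do.call(rbind, truthRows)
  utils::write.table(tab, file.path(outDir, "truth_regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(subjectDirs = dirs, truthTable = tab))
}

#' Simulate a split cohort: subject FA stepped at a Tmax changepoint
#'
#' Each subject receives a continuous true mean Tmax drawn uniformly over
#' `tmaxRange` and a regional FA drawn around `faLow` (below the
#' changepoint) or `faHigh` (at or above it). A single hypoperfused-WM
#' region of `nVoxels` voxels is then pushed through the imaging forward
#' model and recovered: DWI simulation + tensor fit for FA, DSC simulation
#' (under the `"interpolated"` Tmax convention) + block-circulant
#' deconvolution with parabolic peak interpolation for Tmax.
#'
#' @param nSubjects cohort size.
#' @param changepoint Tmax changepoint (s) separating the two FA levels.
#' @param faLow,faHigh subgroup FA means below/at-or-above the changepoint.
#' @param faSD between-subject FA SD within each subgroup.
#' @param tmaxRange range (s) of the uniform subject-level Tmax draw.
#' @param nVoxels voxels per subject region.
#' @param snrDwi DWI signal-to-noise ratio.
#' @param dscNoiseSD DSC signal noise SD.
#' @param voxelSD within-region voxel SDs (named `fa`, `md`, `tmax`).
#' @param scheme an [AcquisitionScheme-class].
#' @param seed integer seed.
#' @return data.frame with one row per subject: planted `trueTmax` and
#'   `trueFa`, and pipeline-recovered `tmax` and `fa` region means.
#' @export
simulateSplitCohort <- function(nSubjects = 21L, changepoint = 5.4,
                                faLow = 0.390, faHigh = 0.423, faSD = 0.014,
                                tmaxRange = c(2, 9), nVoxels = 128L,
                                snrDwi = 30, dscNoiseSD = 1.5,
                                voxelSD = c(fa = 0.010, md = 0.02e-3, tmax = 0.5),
                                scheme = defaultScheme(), seed = 1L) {
  set.seed(seed)
  dm <- defaultDscModel()
  tr <- dscTR(scheme)
  n <- dscTimepoints(scheme)
  t <- (seq_len(n) - 1) * tr
  aif <- gammaVariateAif(t, dm$aifOnset, dm$aifShape, dm$aifScale,
                         dm$aifAmplitude)
  pinv <- blockCirculantPinv(aif, tr, dm$thresholdFrac)
  cal <- tmaxCalibration(scheme, dm, maxDelay = max(tmaxRange) + 4)
  lookup <- cal$lookup
  md <- 0.72e-3
  s0 <- 100

  subjTmax <- stats::runif(nSubjects, tmaxRange[1], tmaxRange[2])
  high <- subjTmax >= changepoint
  subjFa <- rtruncNorm(nSubjects, faLow, faSD, 0.01, 0.95)
  subjFa[high] <- rtruncNorm(sum(high), faHigh, faSD, 0.01, 0.95)

  out <- data.frame(subject = seq_len(nSubjects), trueTmax = subjTmax,
                    trueFa = subjFa, tmax = NA_real_, fa = NA_real_)
  X <- tensorDesign(scheme)
  pinvX <- solve(crossprod(X), t(X))
  gtab <- gradientTable(scheme)
  dirs <- as.matrix(gtab[, c("gx", "gy", "gz")])
  proj2 <- as.numeric(dirs %*% c(0, 0, 1))^2
  for (s in seq_len(nSubjects)) {
    fa_v <- rtruncNorm(nVoxels, subjFa[s], voxelSD["fa"], 0.01, 0.95)
    md_v <- rtruncNorm(nVoxels, md, voxelSD["md"], 1e-4)
    tm_v <- rtruncNorm(nVoxels, subjTmax[s], voxelSD["tmax"], 0)
    # DWI forward + log-linear refit
    ev <- solveEigenvalues(fa_v, md_v)
    expo <- outer(ev[, 2], gtab$bval) +
      outer(ev[, 1] - ev[, 2], gtab$bval * proj2)
    sig <- s0 * exp(-expo)
    if (is.finite(snrDwi)) sig <- addRicianNoise(sig, s0 / snrDwi)
    coef <- log(sig) %*% t(pinvX)
    evr <- pmax(eigSym3(coef[, 2], coef[, 3], coef[, 4],
                        coef[, 5], coef[, 6], coef[, 7]), 0)
    faRec <- faFromEigenvalues(evr[, 1], evr[, 2], evr[, 3])
    # DSC forward + deconvolution
    conc <- concForDelays(lookup, cal$inverse(tm_v))
    sigP <- s0 * exp(-dscTE(scheme) * conc)
    if (dscNoiseSD > 0)
      sigP <- sigP + stats::rnorm(length(sigP), 0, dscNoiseSD)
    concRec <- signalToConcentration(sigP, dscTE(scheme), dm$baselineN)
    k <- pinv %*% rbind(concRec, matrix(0, n, nVoxels))
    tmRec <- tmaxFromResidue(k, tr, n, interpolate = TRUE)
    out$fa[s] <- mean(faRec, na.rm = TRUE)
    out$tmax[s] <- mean(tmRec, na.rm = TRUE)
  }
  out
}

#' Draw bivariate cohorts from a Gaussian copula with given Spearman correlation
#'
#' Samples `n` pairs whose population Spearman correlation is
#' `rhoSpearman`, using the exact Gaussian-copula relation
#' \eqn{\rho_{Pearson} = 2\sin(\pi\rho_S/6)}. Margins are standard normal
#' (Spearman correlation is invariant to monotone margins).
#'
#' @param n number of pairs.
#' @param rhoSpearman target Spearman correlation in (-1, 1).
#' @return data.frame with columns `x` and `y`.
#' @export
copulaPairs <- function(n, rhoSpearman) {
  if (abs(rhoSpearman) >= 1) stop("rhoSpearman must lie in (-1, 1)")
  r <- 2 * sin(pi * rhoSpearman / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  data.frame(x = z1, y = z2)
}
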