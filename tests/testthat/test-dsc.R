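test_that("signalToConcentration inverts the gradient-echo signal model", {
  te <- 0.022
  # constant signal: zero concentration everywhere
  expect_equal(unname(signalToConcentration(rep(80, 40), te)), rep(0, 40),
               ignore_attr = TRUE)

  # a single timepoint at S0*exp(-te*5) maps back to concentration 5
  s <- rep(100, 40); s[20] <- 100 * exp(-te * 5)
  conc <- signalToConcentration(s, te)
  expect_equal(conc[20], 5, tolerance = 1e-12, ignore_attr = TRUE)

  # phantom forward model round trip, noiseless
  spec <- smallSpec()
  sch <- defaultScheme()
  truth <- makeGroundTruth(spec, 5)
  sim <- simulateDsc(spec, sch, truth, 1)
  n <- dscTimepoints(sch)
  vox <- c(10, 6, 3)                 # inside the hypoperfused lesion
  expect_equal(truth@labelMap[vox[1], vox[2], vox[3]], 3L)
  sig <- sim$dsc[vox[1], vox[2], vox[3], ]
  conc <- signalToConcentration(sig, dscTE(sch), 8L)
  dm <- wmIschemia:::defaultDscModel()
  A <- wmIschemia:::circulantAifMatrix(sim$aif, dscTR(sch))
  r <- dm$cbf * wmIschemia:::residueSamples(
    truth@trueTmax[vox[1], vox[2], vox[3]], dscTR(sch), n, dm$mtt)
  expected <- (A %*% rbind(r, matrix(0, n, 1)))[seq_len(n), 1]
  expect_equal(unname(conc), unname(expected), tolerance = 1e-6,
               ignore_attr = TRUE)

  # all-zero voxel is excluded; short baselines are refused
  expect_true(all(is.na(signalToConcentration(numeric(40), te))))
  expect_error(signalToConcentration(rep(1, 40), te, baselineN = 2L),
               "baselineN")
})

test_that("block-circulant deconvolution recovers impulse, shift and scale", {
  sch <- defaultScheme()
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  t <- (seq_len(n) - 1) * tr
  aif <- gammaVariateAif(t)
  pinv <- blockCirculantPinv(aif, tr)

  # tissue = AIF: the residue is an impulse at lag 0
  k <- deconvolveOsvd(aif, aif, tr, pinv = pinv)
  expect_equal(wmIschemia:::tmaxFromResidue(k, tr, n, FALSE), 0)

  # tissue = AIF shifted by m samples: residue argmax at m*TR
  for (m in c(1L, 3L, 5L)) {
    shifted <- c(numeric(m), aif[seq_len(n - m)])
    km <- deconvolveOsvd(shifted, aif, tr, pinv = pinv)
    expect_equal(wmIschemia:::tmaxFromResidue(km, tr, n, FALSE), m * tr)
  }

  # linearity: scaling the tissue curve scales the residue
  k3 <- deconvolveOsvd(3 * aif, aif, tr, pinv = pinv)
  expect_equal(k3, 3 * k, tolerance = 1e-10)

  expect_error(deconvolveOsvd(aif, aif, tr, thresholdFrac = 0), "thresholdFrac")
  expect_error(deconvolveOsvd(aif, aif, tr, thresholdFrac = 1), "thresholdFrac")
  expect_error(blockCirculantPinv(numeric(n), tr), "zero")
  expect_error(deconvolveOsvd(aif[-1], aif, tr), "equal length")
})

test_that("deconvolution is circular-shift equivariant in the padded domain", {
  sch <- defaultScheme()
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  aif <- gammaVariateAif((seq_len(n) - 1) * tr)
  pinv <- blockCirculantPinv(aif, tr)
  set.seed(4)
  cpad <- c(rnorm(n), numeric(n))       # arbitrary padded tissue curve
  k <- pinv %*% cpad
  for (m in c(2L, 17L, 61L)) {
    shift <- function(x) c(x[(2 * n - m + 1):(2 * n)], x[1:(2 * n - m)])
    expect_equal(pinv %*% shift(cpad), shift(k), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("Tmax maps quantize to the grid and flag degenerate residues", {
  sch <- defaultScheme()
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  # impulse residue at lag zero gives Tmax 0
  k0 <- c(1, numeric(2 * n - 1))
  expect_equal(wmIschemia:::tmaxFromResidue(k0, tr, n, FALSE), 0)
  # all-zero residue gives NaN
  expect_true(is.nan(wmIschemia:::tmaxFromResidue(numeric(2 * n), tr, n, FALSE)))

  # planted 4*TR delay recovered as 5.8 s through the full phantom + map path
  spec <- smallSpec()
  spec@regions$tmaxMean <- rep(4 * tr, 4)
  spec@regions$tmaxSD <- rep(0, 4)
  truth <- makeGroundTruth(spec, 3)
  sim <- simulateDsc(spec, sch, truth, 2)
  mask <- truth@labelMap > 0
  sig <- matrix(sim$dsc, prod(dim(mask)), n)
  conc <- signalToConcentration(t(sig[mask, ]), dscTE(sch), 8L)
  k <- deconvolveOsvd(conc, sim$aif, tr)
  tm <- tmaxMap(k, mask, tr, n)
  expect_equal(unique(mapData(tm)[mask]), 5.8, tolerance = 1e-9)
  expect_true(validObject(tm))

  # mask/column mismatch is refused
  expect_error(tmaxMap(k, array(TRUE, c(2, 2, 2)), tr, n), "mask")
})

test_that("recovered Tmax is monotone and exact on the TR grid (noiseless sweep)", {
  sch <- defaultScheme()
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  dm <- wmIschemia:::defaultDscModel()
  aif <- gammaVariateAif((seq_len(n) - 1) * tr)
  A <- wmIschemia:::circulantAifMatrix(aif, tr)
  pinv <- blockCirculantPinv(aif, tr)
  d <- seq(0, 10, by = 0.23)
  r <- dm$cbf * wmIschemia:::residueSamples(d, tr, n, dm$mtt)
  conc <- (A %*% rbind(r, matrix(0, n, length(d))))[seq_len(n), ]
  rec <- wmIschemia:::tmaxFromResidue(
    pinv %*% rbind(conc, matrix(0, n, length(d))), tr, n, FALSE)
  expect_false(is.unsorted(rec))                     # monotone in the delay
  onGrid <- (0:6) * tr
  rg <- dm$cbf * wmIschemia:::residueSamples(onGrid, tr, n, dm$mtt)
  cg <- (A %*% rbind(rg, matrix(0, n, 7)))[seq_len(n), ]
  recg <- wmIschemia:::tmaxFromResidue(
    pinv %*% rbind(cg, matrix(0, n, 7)), tr, n, FALSE)
  expect_equal(recg, onGrid)                          # exact on the grid
})

test_that("Tmax recovery tolerates noise at peak-drop SNR 20", {
  sch <- defaultScheme()
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  dm <- wmIschemia:::defaultDscModel()
  aif <- gammaVariateAif((seq_len(n) - 1) * tr)
  A <- wmIschemia:::circulantAifMatrix(aif, tr)
  pinv <- blockCirculantPinv(aif, tr)
  set.seed(77)
  d <- runif(1000, 0, 8)
  r <- dm$cbf * wmIschemia:::residueSamples(d, tr, n, dm$mtt)
  conc <- (A %*% rbind(r, matrix(0, n, 1000)))[seq_len(n), ]
  s0 <- 100
  sig <- s0 * exp(-dscTE(sch) * conc)
  drop <- s0 - min(sig)
  sig <- sig + rnorm(length(sig), 0, drop / 20)
  concN <- signalToConcentration(sig, dscTE(sch), 8L)
  rec <- wmIschemia:::tmaxFromResidue(
    pinv %*% rbind(concN, matrix(0, n, 1000)), tr, n, FALSE)
  truthGrid <- ceiling(d / tr - 1e-9) * tr            # noiseless quantization
  expect_lte(median(abs(rec - truthGrid)), tr)
})

test_that("interpolated-convention calibration plants recoverable continuous Tmax", {
  sch <- defaultScheme()
  cal <- tmaxCalibration(sch, maxDelay = 11)
  tr <- dscTR(sch); n <- dscTimepoints(sch)
  aif <- gammaVariateAif((seq_len(n) - 1) * tr)
  pinv <- blockCirculantPinv(aif, tr)
  target <- seq(2, 9, by = 0.35)
  conc <- wmIschemia:::concForDelays(cal$lookup, cal$inverse(target))
  rec <- wmIschemia:::tmaxFromResidue(
    pinv %*% rbind(conc, matrix(0, n, length(target))), tr, n, TRUE)
  expect_lt(max(abs(rec - target)), 0.05)

  # delay beyond the acquisition window is refused by the simulator
  spec <- smallSpec()
  spec@regions$tmaxMean <- rep(80, 4)
  truth <- makeGroundTruth(spec, 1)
  expect_error(simulateDsc(spec, defaultScheme(), truth, 1), "window")
})
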