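test_that("solveEigenvalues inverts the FA definition", {
  # isotropic case: all eigenvalues equal the mean diffusivity
  ev <- solveEigenvalues(0, 0.7e-3)
  expect_equal(as.numeric(ev), rep(0.7e-3, 3))

  # round trip through the FA formula for a spread of targets, including
  # the planted regional means
  fa <- c(0.05, 0.15, 0.313, 0.360, 0.397, 0.6, 0.9, 0.99)
  md <- c(0.4e-3, 0.5e-3, 0.72e-3, 0.75e-3, 0.8e-3, 1e-3, 1.2e-3, 2e-3)
  ev <- solveEigenvalues(fa, md)
  expect_equal(faFromEigenvalues(ev[, 1], ev[, 2], ev[, 3]), fa,
               tolerance = 1e-10)
  expect_equal(adcFromEigenvalues(ev[, 1], ev[, 2], ev[, 3]), md,
               tolerance = 1e-12)
  expect_true(all(ev[, 1] >= ev[, 2] & ev[, 2] == ev[, 3] & ev[, 3] >= 0))

  # limiting case: fa -> 1 drives the radial eigenvalues to zero
  ev <- solveEigenvalues(c(0.99, 0.999, 0.9999), 0.7e-3)
  expect_true(all(diff(ev[, 2]) < 0))
  expect_lt(ev[3, 2], 1e-3 * 0.7e-3)

  expect_error(solveEigenvalues(1, 0.7e-3), "fa")
  expect_error(solveEigenvalues(-0.1, 0.7e-3), "fa")
  expect_error(solveEigenvalues(0.3, 0), "md")
})

test_that("simulateDwi produces the tensor-model signal and is deterministic", {
  spec <- smallSpec()
  sch <- defaultScheme()
  truth <- makeGroundTruth(spec, 5)

  # isotropic compartments: every diffusion-weighted signal is s0*exp(-b*md)
  iso <- spec
  iso@regions$faMean <- rep(0, 4)
  iso@regions$faSD <- rep(0, 4)
  truthIso <- makeGroundTruth(iso, 5)
  dwi <- simulateDwi(iso, sch, truthIso, 1)
  gt <- gradientTable(sch)
  dw <- which(gt$bval > 0)
  v <- dwi[8, 8, 4, ]
  expected <- 100 * exp(-gt$bval * truthIso@trueAdc[8, 8, 4])
  expect_equal(v, expected, tolerance = 1e-12)

  # determinism
  expect_identical(simulateDwi(spec, sch, truth, 3),
                   simulateDwi(spec, sch, truth, 3))
  spec30 <- smallSpec(snrDwi = 30)
  expect_identical(simulateDwi(spec30, sch, truth, 3),
                   simulateDwi(spec30, sch, truth, 3))
  expect_false(identical(simulateDwi(spec30, sch, truth, 3),
                         simulateDwi(spec30, sch, truth, 4)))

  # grid mismatch is refused
  other <- makeGroundTruth(smallSpec(gridShape = c(8L, 8L, 8L)), 5)
  expect_error(simulateDwi(spec, sch, other, 1), "grid")
})

test_that("noiseless phantom pipeline recovers the planted tensor to 1e-8", {
  spec <- smallSpec()
  sch <- defaultScheme()
  truth <- makeGroundTruth(spec, 9)
  dwi <- simulateDwi(spec, sch, truth, 2)
  maps <- computeMaps(dwi, sch)
  expect_lt(max(abs(mapData(maps$fa) - truth@trueFa)), 1e-8)
  expect_lt(max(abs(mapData(maps$adc) - truth@trueAdc)), 1e-8)
})

test_that("Rician noise inflates FA in an isotropic region (noise floor)", {
  spec <- smallSpec(snrDwi = 30)
  spec@regions$faMean <- rep(0, 4)
  spec@regions$faSD <- rep(0, 4)
  sch <- defaultScheme()
  truth <- makeGroundTruth(spec, 3)
  maps <- computeMaps(simulateDwi(spec, sch, truth, 21), sch)
  expect_gt(mean(mapData(maps$fa)), 0)   # sign of the bias only
})

test_that("ground truth draws respect their distributions and determinism", {
  spec <- smallSpec(nSubjects = 21L)
  spec@regions$faSD <- spec@regions$mdSD <- spec@regions$tmaxSD <- rep(0, 4)

  # zero-SD spec: all subjects share identical truths
  t1 <- makeGroundTruth(spec, 4)
  t2 <- makeGroundTruth(spec, 99)
  expect_identical(t1@trueFa, t2@trueFa)

  # same seed twice: identical maps
  specSD <- smallSpec()
  specSD@regions <- defaultRegionParams()
  expect_identical(makeGroundTruth(specSD, 7), makeGroundTruth(specSD, 7))

  # cohort means of subject-level draws sit within 3 SE of the configured
  # regional means
  draws <- do.call(rbind, lapply(1:21, function(s)
    makeGroundTruth(specSD, 1000 + s)@subjectRegions))
  r <- defaultRegionParams()
  for (i in seq_len(nrow(r))) {
    m <- mean(draws$fa[draws$region == r$label[i]])
    se <- r$faSD[i] / sqrt(21)
    expect_lt(abs(m - r$faMean[i]), 3 * se + 1e-12)
  }

  # every labeled voxel carries finite truth values (class validity)
  expect_true(validObject(makeGroundTruth(specSD, 8)))
})

test_that("generateCohort writes bundles that read back losslessly", {
  dir <- withr::local_tempdir()
  spec <- smallSpec(nSubjects = 2L)
  out <- generateCohort(spec, dir)
  expect_length(out$subjectDirs, 2)
  expect_true(file.exists(file.path(dir, "truth_regions.tsv")))

  b <- simulateSubject(spec, defaultScheme(), 1L)
  dwi <- readVolume(file.path(out$subjectDirs[1], "dwi.nii.gz"), 4L)
  expect_equal(dwi$data, b$dwi, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(dwi$voxelSize, c(1.5, 1.5, 3))
  lab <- readVolume(file.path(out$subjectDirs[1], "labels.nii.gz"), 3L)
  expect_equal(array(as.integer(lab$data), dim(lab$data)), b$truth@labelMap,
               ignore_attr = TRUE)

  # unwritable destination (parent is a plain file) is an error
  f <- file.path(dir, "blocker")
  writeLines("x", f)
  suppressWarnings(expect_error(generateCohort(spec, file.path(f, "cohort")),
                                "cannot create"))
})

test_that("copulaPairs hits the requested Spearman correlation in the large-n limit", {
  set.seed(42)
  p <- copulaPairs(20000, 0.561)
  expect_lt(abs(spearmanCor(p$x, p$y)$rho - 0.561), 0.02)
  expect_error(copulaPairs(10, 1.2), "rhoSpearman")
})
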