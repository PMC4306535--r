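# Shared fixtures: small, fast phantom specifications built in code.

smallSpec <- function(..., gridShape = c(16L, 16L, 8L), nSubjects = 3L,
                      snrDwi = Inf, dscNoiseSD = 0,
                      voxelSD = c(fa = 0, md = 0, tmax = 0), seed = 11L) {
  defaultPhantomSpec(nSubjects = nSubjects, gridShape = gridShape,
                     snrDwi = snrDwi, dscNoiseSD = dscNoiseSD,
                     voxelSD = voxelSD, seed = seed, ...)
}

# Deterministic general (not axially symmetric) diffusion tensor.
randomSPDTensor <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  q %*% diag(c(1.6e-3, 0.7e-3, 0.3e-3)) %*% t(q)
}

# Forward DWI signals for an arbitrary 3x3 tensor under a scheme.
signalsForTensor <- function(D, scheme, s0 = 100) {
  gt <- gradientTable(scheme)
  g <- as.matrix(gt[, c("gx", "gy", "gz")])
  quad <- rowSums((g %*% D) * g)
  s0 * exp(-gt$bval * quad)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
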