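# Internal numerical helpers.

# Eigenvalues of many symmetric 3x3 matrices at once, via the trigonometric
# closed form (no per-voxel eigen() calls). Inputs are vectors of the six
# unique components; returns an n x 3 matrix, eigenvalues in descending
# order. Accurate to ~1e-12 relative, which is far below any noise level
# the maps carry.
eigSym3 <- function(dxx, dyy, dzz, dxy, dxz, dyz) {
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  n <- length(q)
  out <- matrix(q, n, 3)
  nz <- p > 0 & is.finite(p)
  if (any(nz)) {
    pn <- p[nz]
    bxx <- (dxx[nz] - q[nz]) / pn
    byy <- (dyy[nz] - q[nz]) / pn
    bzz <- (dzz[nz] - q[nz]) / pn
    bxy <- dxy[nz] / pn
    bxz <- dxz[nz] / pn
    byz <- dyz[nz] / pn
    detB <- bxx * (byy * bzz - byz^2) -
      bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * pn * cos(phi)
    e3 <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    out[nz, 1] <- e1
    out[nz, 2] <- e2
    out[nz, 3] <- e3
  }
  bad <- !is.finite(q)
  if (any(bad)) out[bad, ] <- NA_real_
  out
}

# Truncated-normal draws by rejection; fine for the modest truncations the
# phantom uses (bounds are always >= ~2 SD from the mean on at most one side).
rtruncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) {  # pathological truncation; clamp rather than spin
      out[bad] <- pmin(pmax(out[bad], lower), upper)
      break
    }
  }
  out
}

# Rician corruption of a magnitude image: sqrt((S + n1)^2 + n2^2) with
# iid Gaussian n1, n2 of the given SD.
addRicianNoise <- function(signal, sd) {
  if (sd == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

# Lower-triangular Toeplitz convolution matrix T with T[i, j] = dt * a[i-j+1],
# so that (T %*% r) is the causal discrete convolution dt * sum a_k r_{i-k}.
convMatrix <- function(a, dt) {
  n <- length(a)
  idx <- outer(seq_len(n), seq_len(n), `-`) + 1L
  m <- matrix(0, n, n)
  keep <- idx >= 1L
  m[keep] <- a[idx[keep]]
  m * dt
}

# Derive a per-subject (or per-replicate) seed from a base seed, keeping the
# result inside the 32-bit integer range.
deriveSeed <- function(base, k) {
  as.integer((as.numeric(base) * 1009 + k * 9973) %% 2147483647)
}
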