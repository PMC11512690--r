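# Shared fixtures and independent oracles, built in code at test time.

# Quadrature oracle for the spherical mean of exp(-x cos^2 theta):
# with t = cos(theta), the orientation average is int_0^1 exp(-x t^2) dt.
quadKernelMean <- function(x) {
  vapply(x, function(xx)
    integrate(function(t) exp(-xx * t^2), 0, 1, rel.tol = 1e-12)$value, 0)
}

# Quadrature oracle for the two-compartment spherical-mean signal: each
# compartment integrated over orientation independently of the package's
# erf/Taylor evaluation.
quadModelSignal <- function(b, v, lambda) {
  lperp <- (1 - v) * lambda
  intra <- quadKernelMean(b * lambda)
  extra <- exp(-b * lperp) * quadKernelMean(b * (lambda - lperp))
  v * intra + (1 - v) * extra
}

# Noise-free single-tensor DWI over nvox identical voxels.
makeTensorDWI <- function(D = c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0),
                          S0 = 1000, ndir = 30, bval = 1000, nb0 = 3,
                          dims = c(1L, 1L, 1L), seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(3 * ndir), nrow = 3)
  dirs <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  bvals <- c(rep(0, nb0), rep(bval, ndir))
  bvecs <- cbind(matrix(0, 3, nb0), dirs)
  Dm <- matrix(c(D[1], D[4], D[5], D[4], D[2], D[6], D[5], D[6], D[3]), 3, 3)
  att <- exp(-bvals * colSums(bvecs * (Dm %*% bvecs)))
  att[bvals == 0] <- 1
  sig <- array(rep(S0 * att, each = prod(dims)), c(dims, length(bvals)))
  new("DWIVolume", signal = sig, affine = diag(4),
      gradients = gradientTable(bvals, bvecs))
}

# Single-voxel spherical-mean profile from explicit values.
makeProfile <- function(shellB, means) {
  new("SphericalMeanProfile",
      means = array(means, c(1L, 1L, 1L, length(shellB))),
      shellB = shellB, clipped = array(FALSE, c(1L, 1L, 1L)),
      excluded = array(FALSE, c(1L, 1L, 1L)), affine = diag(4))
}

# Constant-tensor field on a grid (all voxels fitted).
makeTensorField <- function(D, dims = c(4L, 4L, 2L)) {
  arr <- array(rep(D, each = prod(dims)), c(dims, 6L))
  new("TensorField", D = arr, logS0 = array(log(1000), dims),
      affine = diag(4), fitMask = array(TRUE, dims))
}

# Simple two-hemisphere ROI set on a grid split along x.
makeROIs <- function(dims = c(4L, 4L, 2L), voxelVolume = 1) {
  half <- dims[1] %/% 2
  m <- function(xr, zr) {
    a <- array(FALSE, dims)
    a[xr, , zr] <- TRUE
    a
  }
  fibreROISet(m(1:half, 1), m(1:half, 2),
              m((half + 1):dims[1], 1), m((half + 1):dims[1], 2),
              voxelVolume)
}
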