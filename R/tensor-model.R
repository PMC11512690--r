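#' @include AllClasses.R AllGenerics.R protocol-io.R
NULL

# Design row for the log-linear tensor model:
# log S = log S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                     + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
tensorDesign <- function(bvals, bvecs) {
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  cbind(1,
        -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
        -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
}

#' Fit a single diffusion tensor per voxel
#'
#' Fits the log-linear tensor model to the b0 volumes plus one shell
#' (by convention the b=1000 s/mm^2 shell) by ordinary least squares,
#' followed by one weighted refit with weights equal to the squared
#' predicted signals — the usual variance-stabilizing compromise for
#' log-transformed Rician-corrupted magnitudes. Other shells are ignored.
#'
#' @param dwi a [DWIVolume-class]
#' @param mask logical 3-D array of voxels to fit (default: all voxels with
#'   any non-zero signal)
#' @param shellB nominal b-value of the shell used (s/mm^2, default 1000)
#' @param signalFloorFrac signals at or below
#'   \code{signalFloorFrac * mean(b0)} are raised to that floor before the
#'   log (default 1e-6)
#' @return a [TensorField-class]; voxels whose signals are all zero are
#'   dropped from \code{fitMask}
#' @export
fitTensor <- function(dwi, mask = NULL, shellB = 1000,
                      signalFloorFrac = 1e-6) {
  stopifnot(is(dwi, "DWIVolume"))
  grouping <- groupShells(dwi)
  if (length(grouping@b0Indices) < 1L)
    stop("protocol error: no b0 volumes")
  tol <- dwi@gradients@shellTolerance
  hit <- which(vapply(grouping@shells,
                      function(s) abs(s$b - shellB) <= tol, FALSE))
  if (length(hit) == 0L)
    stop(sprintf("protocol error: no shell at nominal b = %g", shellB))
  shellIdx <- grouping@shells[[hit[1]]]$indices
  if (length(shellIdx) < 6L)
    stop(sprintf("protocol error: shell b = %g has %d directions (< 6)",
                 shellB, length(shellIdx)))
  use <- c(grouping@b0Indices, shellIdx)
  if (length(use) < 7L)
    stop(sprintf("protocol error: %d usable volumes (< 7)", length(use)))

  dims <- dim(dwi@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))

  X <- tensorDesign(dwi@gradients@bvals[use],
                    dwi@gradients@bvecs[, use, drop = FALSE])
  sig <- matrix(dwi@signal, prod(dims), dim(dwi@signal)[4])[, use,
                                                            drop = FALSE]
  vox <- which(as.vector(mask) & rowSums(sig) > 0)
  s0mean <- mean(sig[vox, seq_along(grouping@b0Indices), drop = FALSE])
  floor <- signalFloorFrac * s0mean
  Y <- t(log(pmax(sig[vox, , drop = FALSE], floor)))  # nvol x nvox

  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)                      # 7 x nvox, OLS pass
  for (j in seq_along(vox)) {                          # WLS refit per voxel
    w <- exp(X %*% B[, j])^2
    Xw <- X * as.vector(w)
    Bw <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, Y[, j])),
                   error = function(e) NULL)
    if (!is.null(Bw)) B[, j] <- Bw
  }

  D <- array(0, c(dims, 6L))
  logS0 <- array(NA_real_, dims)
  Dflat <- matrix(D, prod(dims), 6L)
  Dflat[vox, ] <- t(B[2:7, , drop = FALSE])
  D <- array(Dflat, c(dims, 6L))
  logS0[vox] <- B[1, ]
  fitMask <- array(FALSE, dims)
  fitMask[vox] <- TRUE
  new("TensorField", D = D, logS0 = logS0, affine = dwi@affine,
      fitMask = fitMask)
}

#' Eigendecomposition of a tensor field
#'
#' @param t a [TensorField-class]
#' @param eigenFloor eigenvalues below this (mm^2/s) are clamped to it and
#'   the voxel flagged (default 1e-9)
#' @return a list with \code{values} (x, y, z, 3 array, descending),
#'   \code{vectors} (x, y, z, 3, 3 array; \code{[.., , k]} is the k-th
#'   eigenvector), \code{clamped} (logical 3-D array) and \code{affine}
#' @export
tensorEigensystem <- function(t, eigenFloor = 1e-9) {
  stopifnot(is(t, "TensorField"))
  dims <- dim(t@D)[1:3]
  vals <- array(NA_real_, c(dims, 3L))
  vecs <- array(NA_real_, c(dims, 3L, 3L))
  clamped <- array(FALSE, dims)
  vox <- which(t@fitMask)
  n <- prod(dims)
  Dflat <- matrix(t@D, n, 6L)
  valsFlat <- matrix(NA_real_, n, 3L)
  vecsFlat <- matrix(NA_real_, n, 9L)
  for (i in vox) {
    d <- Dflat[i, ]
    M <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3L, 3L)
    e <- eigen(M, symmetric = TRUE)
    lv <- e$values
    if (any(lv < eigenFloor)) {
      clamped[i] <- TRUE
      lv <- pmax(lv, eigenFloor)
    }
    valsFlat[i, ] <- lv
    vecsFlat[i, ] <- as.vector(e$vectors)
  }
  vals <- array(valsFlat, c(dims, 3L))
  vecs <- array(vecsFlat, c(dims, 3L, 3L))
  list(values = vals, vectors = vecs, clamped = clamped, affine = t@affine)
}

#' FA and MD maps from per-voxel eigenvalues
#'
#' MD is the eigenvalue mean; FA uses the sqrt(3/2)-normalized form with
#' range \[0, 1\]:
#' FA = sqrt(3/2) * sqrt(sum((l_i - MD)^2)) / sqrt(sum(l_i^2)),
#' defined as 0 for an all-zero triple.
#'
#' @param eig eigensystem list from [tensorEigensystem()], or any list with
#'   a \code{values} (x, y, z, 3) array and an \code{affine}
#' @return list with \code{FA} and \code{MD} [ScalarMap-class] objects
#' @export
faMD <- function(eig) {
  vals <- eig$values
  dims <- dim(vals)[1:3]
  lam <- matrix(vals, prod(dims), 3L)
  md <- rowMeans(lam)
  num <- sqrt(rowSums((lam - md)^2))
  den <- sqrt(rowSums(lam^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa[!is.finite(md)] <- NA_real_
  md[!is.finite(md)] <- NA_real_
  fa <- pmin(pmax(fa, 0), 1)
  list(FA = new("ScalarMap", values = array(fa, dims), affine = eig$affine,
                meaning = "FA"),
       MD = new("ScalarMap", values = array(md, dims), affine = eig$affine,
                meaning = "MD"))
}
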