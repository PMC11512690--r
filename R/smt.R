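#' @include AllClasses.R protocol-io.R
NULL

#' Spherical mean of the axially symmetric attenuation kernel
#'
#' \code{smtKernelMean(x)} is the orientation average of
#' \code{exp(-x * cos(theta)^2)} over the sphere:
#' sqrt(pi / (4 x)) * erf(sqrt(x)). For small x the closed form is
#' numerically unstable, so a Taylor branch
#' 1 - x/3 + x^2/10 - x^3/42 is used below \code{xSwitch}
#' (truncation error < 1e-24 at the default switch).
#'
#' @param x non-negative argument (b-value times diffusivity contrast,
#'   dimensionless); vectorized
#' @param xSwitch branch point (default 1e-5)
#' @return spherical-mean attenuation in (0, 1]
#' @export
smtKernelMean <- function(x, xSwitch = 1e-5) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x <= xSwitch
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 10 - xs^3 / 42
  xl <- x[!small]
  # erf(s) = 2 pnorm(s sqrt(2)) - 1
  out[!small] <- sqrt(pi / (4 * xl)) * (2 * pnorm(sqrt(2 * xl)) - 1)
  out
}

#' Two-compartment spherical-mean model signal
#'
#' Normalized spherical-mean signal of the stick + tortuosity-zeppelin
#' model. The intra-neurite compartment is a stick (no transverse
#' diffusivity); intra- and extra-neurite longitudinal diffusivities are
#' equal (lambda); the extra-neurite transverse diffusivity follows the
#' tortuosity relation lambda_perp = (1 - v) * lambda. Then
#' \deqn{\bar e(b; v, \lambda) = v\,c(b\lambda) +
#'   (1-v)\,e^{-b(1-v)\lambda} c(b v \lambda)}
#' with c(x) the kernel mean of [smtKernelMean()].
#'
#' @param b b-value(s) in ms/um^2 (1000 s/mm^2 = 1 ms/um^2)
#' @param v intra-neurite volume fraction in \[0, 1\]
#' @param lambda intrinsic diffusivity in um^2/ms (> 0)
#' @return normalized mean signal(s); exactly 1 at b = 0
#' @export
smtModelSignal <- function(b, v, lambda) {
  stopifnot(all(b >= 0), v >= 0, v <= 1, lambda > 0)
  v * smtKernelMean(b * lambda) +
    (1 - v) * exp(-b * (1 - v) * lambda) * smtKernelMean(b * v * lambda)
}

#' Per-shell spherical-mean signals, normalized by b0
#'
#' Per voxel, e(b) = mean(shell signals) / mean(b0 signals). Shell b-values
#' are converted to ms/um^2 for downstream model fitting. Voxels whose mean
#' b0 signal is zero are excluded and flagged; shell means at or below
#' \code{clipFloor} are clipped up to it and the voxel flagged.
#'
#' @param dwi a [DWIVolume-class]
#' @param grouping optional [ShellGrouping-class] (computed if missing)
#' @param mask logical 3-D array (default all voxels)
#' @param clipFloor lower clip for normalized means (default 1e-6)
#' @return a [SphericalMeanProfile-class]
#' @export
sphericalMeans <- function(dwi, grouping = NULL, mask = NULL,
                           clipFloor = 1e-6) {
  stopifnot(is(dwi, "DWIVolume"))
  if (is.null(grouping)) grouping <- groupShells(dwi)
  if (length(grouping@b0Indices) < 1L || length(grouping@shells) < 1L)
    stop("protocol error: need at least one b0 volume and one shell")
  nd <- vapply(grouping@shells, function(s) length(s$indices), 0L)
  if (any(nd < 15L))
    stop("protocol error: a shell has fewer than 15 directions")
  if (any(nd < 30L))
    warning("shell(s) with fewer than 30 directions: spherical means will be noisy")
  dims <- dim(dwi@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  n <- prod(dims)
  sig <- matrix(dwi@signal, n, dim(dwi@signal)[4])
  b0 <- rowMeans(sig[, grouping@b0Indices, drop = FALSE])
  excluded <- array(FALSE, dims)
  excluded[mask & b0 <= 0] <- TRUE
  use <- as.vector(mask) & b0 > 0
  nshell <- length(grouping@shells)
  means <- array(NA_real_, c(dims, nshell))
  clipped <- array(FALSE, dims)
  mflat <- matrix(means, n, nshell)
  for (k in seq_len(nshell)) {
    sm <- rowMeans(sig[, grouping@shells[[k]]$indices, drop = FALSE]) / b0
    low <- use & sm <= clipFloor
    sm[low] <- clipFloor
    clipped[low] <- TRUE
    mflat[use, k] <- sm[use]
  }
  means <- array(mflat, c(dims, nshell))
  shellB <- vapply(grouping@shells, `[[`, 0, "b") / 1000  # -> ms/um^2
  new("SphericalMeanProfile", means = means, shellB = shellB,
      clipped = clipped, excluded = excluded, affine = dwi@affine)
}

# Model signals for a (v, lambda) grid at the given shells: rows = grid
# points, cols = shells.
smtGridSignals <- function(vGrid, lambdaGrid, shellB) {
  pars <- expand.grid(v = vGrid, lambda = lambdaGrid)
  M <- matrix(0, nrow(pars), length(shellB))
  for (k in seq_along(shellB))
    M[, k] <- mapply(function(v, l) smtModelSignal(shellB[k], v, l),
                     pars$v, pars$lambda)
  list(pars = pars, M = M)
}

#' Fit the two-compartment spherical-mean model per voxel
#'
#' Minimizes the sum over shells of squared differences between observed
#' and model spherical means over v in \[0, 1\] and lambda in
#' \[lambdaMin, lambdaMax\]. Initialization is a coarse grid
#' (v = 0.05..0.95 step 0.1, lambda = 0.25..3.0 step 0.25), refined by
#' box-constrained L-BFGS-B. The extra-neurite mean diffusivity is the
#' derived quantity exmd = lambda * (3 - 2 v) / 3.
#'
#' @param profile a [SphericalMeanProfile-class] with at least 2 shells
#' @param lambdaMin,lambdaMax intrinsic-diffusivity bounds in um^2/ms
#'   (defaults 0.01 and 3.0, the free-water ceiling at body temperature)
#' @return an [SMTFit-class]
#' @export
fitSMT <- function(profile, lambdaMin = 0.01, lambdaMax = 3.0) {
  stopifnot(is(profile, "SphericalMeanProfile"))
  shellB <- profile@shellB
  if (length(shellB) < 2L)
    stop("need at least 2 shells to fit 2 parameters")
  dims <- dim(profile@means)[1:3]
  n <- prod(dims)
  E <- matrix(profile@means, n, length(shellB))
  vox <- which(rowSums(is.finite(E)) == length(shellB) &
                 !as.vector(profile@excluded))

  grid <- smtGridSignals(seq(0.05, 0.95, by = 0.1),
                         seq(0.25, lambdaMax, by = 0.25), shellB)
  # RSS between every grid point and every voxel, via the expansion
  # ||m - e||^2 = ||m||^2 - 2 m.e + ||e||^2
  M2 <- rowSums(grid$M^2)
  E2 <- rowSums(E[vox, , drop = FALSE]^2)
  cross <- grid$M %*% t(E[vox, , drop = FALSE])
  best <- apply(M2 - 2 * cross + rep(E2, each = nrow(grid$M)), 2,
                which.min)

  v <- array(NA_real_, dims); lambda <- array(NA_real_, dims)
  rss <- array(NA_real_, dims); conv <- array(FALSE, dims)
  obj <- function(p, e) sum((smtModelSignal(shellB, p[1], p[2]) - e)^2)
  for (j in seq_along(vox)) {
    i <- vox[j]
    e <- E[i, ]
    p0 <- c(grid$pars$v[best[j]], grid$pars$lambda[best[j]])
    fit <- optim(p0, obj, e = e, method = "L-BFGS-B",
                 lower = c(0, lambdaMin), upper = c(1, lambdaMax),
                 control = list(factr = 1e4))
    v[i] <- fit$par[1]
    lambda[i] <- fit$par[2]
    rss[i] <- fit$value
    conv[i] <- fit$convergence == 0L
  }
  flags <- array(TRUE, dims)
  flags[vox] <- FALSE
  new("SMTFit", v = v, lambda = lambda, exmd = lambda * (3 - 2 * v) / 3,
      rss = rss, converged = conv, flags = flags, affine = profile@affine)
}

#' INVF and exMD scalar maps from a spherical-mean fit
#'
#' exMD is exported in mm^2/s (internal um^2/ms times 1e-3). Flagged voxels
#' carry NaN in both maps; the exclusion mask is returned alongside.
#'
#' @param fits an [SMTFit-class]
#' @return list with \code{INVF} and \code{exMD} [ScalarMap-class] objects
#'   and \code{excluded}, the logical exclusion mask
#' @export
smtMaps <- function(fits) {
  stopifnot(is(fits, "SMTFit"))
  v <- fits@v; ex <- fits@exmd * 1e-3
  v[fits@flags] <- NaN
  ex[fits@flags] <- NaN
  list(INVF = new("ScalarMap", values = v, affine = fits@affine,
                  meaning = "INVF"),
       exMD = new("ScalarMap", values = ex, affine = fits@affine,
                  meaning = "exMD"),
       excluded = fits@flags)
}
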