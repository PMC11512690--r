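#' @include AllClasses.R protocol-io.R smt.R
NULL

# Seeded uniform directions on the unit sphere: normalized standard-normal
# 3-vectors.
uniformSphere <- function(n) {
  m <- matrix(rnorm(3 * n), nrow = 3)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Specify a multi-shell DWI phantom
#'
#' Regions are given as a list; each entry has a \code{name}, a logical
#' \code{mask} on the grid, a \code{type} of "tensor", "smt" or "csf", and
#' the corresponding parameters: \code{D} (length-6 tensor, mm^2/s, order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), or \code{v}/\code{lambda} (um^2/ms) and
#' \code{nFibreDirs} (number of fibre orientations per voxel; \code{Inf}
#' means a fully dispersed orientation distribution, whose per-direction
#' signal equals the analytic spherical mean), or \code{dIso} (mm^2/s).
#'
#' @param gridDim integer length-3 grid shape
#' @param voxelSize isotropic voxel size in mm (default 1.25, the HCP
#'   protocol)
#' @param regions list of region descriptors (pairwise disjoint masks)
#' @param bvals nominal shell b-values in s/mm^2
#' @param directionsPerShell directions per shell (default 90)
#' @param nB0 number of b=0 volumes (default 18)
#' @param S0 non-weighted signal level (default 1000)
#' @param snr S0 / sigma for Rician noise; \code{Inf} = noise-free
#' @param noise "rician" (magnitude of a complex Gaussian-perturbed signal)
#'   or "gaussian" (debugging aid)
#' @param seed RNG seed
#' @return a phantom spec list
#' @export
phantomSpec <- function(gridDim, voxelSize = 1.25, regions,
                        bvals = c(1000, 2000, 3000),
                        directionsPerShell = 90, nB0 = 18, S0 = 1000,
                        snr = 50, noise = c("rician", "gaussian"),
                        seed = 1) {
  noise <- match.arg(noise)
  stopifnot(length(gridDim) == 3L, snr > 0)
  cover <- array(0L, gridDim)
  for (r in regions) {
    stopifnot(identical(dim(r$mask), as.integer(gridDim)) ||
                identical(dim(r$mask), gridDim))
    cover <- cover + r$mask
  }
  if (any(cover > 1L)) stop("spec error: overlapping regions")
  list(gridDim = as.integer(gridDim), voxelSize = voxelSize,
       regions = regions, bvals = bvals,
       directionsPerShell = directionsPerShell, nB0 = nB0, S0 = S0,
       snr = snr, noise = noise, seed = seed)
}

# Noise-free signal of one smt voxel for all DW directions of one shell.
# Equal-weight stick + tortuosity-zeppelin averaged over the voxel's fibre
# directions; bInternal in ms/um^2, lambda in um^2/ms.
smtVoxelSignal <- function(bInternal, gdirs, fibreDirs, v, lambda) {
  lperp <- (1 - v) * lambda
  ct2 <- crossprod(gdirs, fibreDirs)^2        # ndir x nfib, cos^2 angles
  stick <- exp(-bInternal * lambda * ct2)
  zepp <- exp(-bInternal * (lperp + (lambda - lperp) * ct2))
  rowMeans(v * stick + (1 - v) * zepp)
}

#' Generate a multi-shell DWI phantom with known ground truth
#'
#' Tensor regions emit S = S0 exp(-b g' D g); smt regions emit the
#' equal-weight stick + tortuosity-zeppelin mixture averaged over the
#' voxel's fibre orientations (drawn uniformly on the sphere per voxel, or
#' the analytic orientation average when \code{nFibreDirs = Inf}); csf
#' regions decay isotropically. Rician noise replaces each magnitude by
#' |signal + complex Gaussian noise in quadrature| with sigma = S0 / snr.
#'
#' @param spec a [phantomSpec()] list
#' @return list with \code{dwi} ([DWIVolume-class]), \code{labels}
#'   (integer ground-truth region array, 1-based in region order),
#'   \code{truth} (the region descriptors plus protocol echo)
#' @export
makePhantom <- function(spec) {
  set.seed(spec$seed)
  nShell <- length(spec$bvals)
  ndir <- spec$directionsPerShell
  bvals <- c(rep(0, spec$nB0), rep(spec$bvals, each = ndir))
  bvecs <- matrix(0, 3, spec$nB0)
  for (k in seq_len(nShell)) bvecs <- cbind(bvecs, uniformSphere(ndir))
  gt <- gradientTable(bvals, bvecs)
  nvol <- length(bvals)
  dims <- spec$gridDim
  sig <- array(0, c(dims, nvol))
  sigFlat <- matrix(sig, prod(dims), nvol)
  labels <- array(0L, dims)
  dw <- bvals > 0

  for (ri in seq_along(spec$regions)) {
    r <- spec$regions[[ri]]
    vox <- which(r$mask)
    labels[vox] <- ri
    if (r$type == "tensor") {
      d <- r$D
      Dm <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]),
                   3, 3)
      att <- exp(-bvals * colSums(bvecs * (Dm %*% bvecs)))
      att[!dw] <- 1
      sigFlat[vox, ] <- matrix(spec$S0 * att, length(vox), nvol,
                               byrow = TRUE)
    } else if (r$type == "csf") {
      att <- exp(-bvals * r$dIso)
      att[!dw] <- 1
      sigFlat[vox, ] <- matrix(spec$S0 * att, length(vox), nvol,
                               byrow = TRUE)
    } else if (r$type == "smt") {
      sigFlat[vox, !dw] <- spec$S0
      if (is.infinite(r$nFibreDirs)) {
        for (k in seq_len(nShell)) {
          idx <- which(dw & abs(bvals - spec$bvals[k]) < 1e-9)
          e <- smtModelSignal(spec$bvals[k] / 1000, r$v, r$lambda)
          sigFlat[vox, idx] <- spec$S0 * e
        }
      } else {
        for (j in vox) {
          fd <- uniformSphere(r$nFibreDirs)
          for (k in seq_len(nShell)) {
            idx <- which(dw & abs(bvals - spec$bvals[k]) < 1e-9)
            sigFlat[j, idx] <- spec$S0 *
              smtVoxelSignal(spec$bvals[k] / 1000, bvecs[, idx], fd,
                             r$v, r$lambda)
          }
        }
      }
    } else stop(sprintf("unknown region type '%s'", r$type))
  }

  if (is.finite(spec$snr)) {
    sigma <- spec$S0 / spec$snr
    inRegion <- which(labels != 0L)
    nv <- length(inRegion) * nvol
    if (spec$noise == "rician") {
      sigFlat[inRegion, ] <- sqrt(
        (sigFlat[inRegion, ] + rnorm(nv, 0, sigma))^2 +
          rnorm(nv, 0, sigma)^2)
    } else {
      sigFlat[inRegion, ] <- pmax(0, sigFlat[inRegion, ] +
                                    rnorm(nv, 0, sigma))
    }
  }

  affine <- diag(c(rep(spec$voxelSize, 3), 1))
  dwi <- new("DWIVolume", signal = array(sigFlat, c(dims, nvol)),
             affine = affine, gradients = gt)
  list(dwi = dwi, labels = labels,
       truth = list(regions = spec$regions, bvals = spec$bvals,
                    directionsPerShell = ndir, nB0 = spec$nB0,
                    S0 = spec$S0, snr = spec$snr, seed = spec$seed))
}

#' Default phantom spec: slab phantom on a 20 x 20 x 12 grid
#'
#' Four z-slabs: a projection-fibre tensor slab (head-foot oriented), an
#' association-fibre tensor slab (anterior-posterior oriented), an smt slab
#' and a csf slab. Left/right hemispheres are the x < and >= midline
#' halves; the ALPS fibre ROIs are the tensor slabs split by hemisphere.
#'
#' @param snr S0/sigma (default 50, a typical b0 SNR for the emulated
#'   3T protocol); \code{Inf} = noise-free
#' @param v,lambda smt slab parameters (defaults 0.6 and 2.0 um^2/ms)
#' @param nFibreDirs fibre orientations per smt voxel (default Inf,
#'   fully dispersed)
#' @param dxBoost added to Dxx of both fibre slabs (mm^2/s): the
#'   perivascular x-axis diffusivity contribution (default 0.4e-3)
#' @param seed RNG seed
#' @param gridDim grid shape (default c(20, 20, 12))
#' @return list with \code{spec}, \code{rois} ([FibreROISet-class]) and
#'   \code{expectedIndex}, the analytically composed ALPS index
#' @export
defaultPhantomSpec <- function(snr = 50, v = 0.6, lambda = 2.0,
                               nFibreDirs = Inf, dxBoost = 0.4e-3,
                               seed = 1, gridDim = c(20L, 20L, 12L)) {
  slab <- function(zRange) {
    m <- array(FALSE, gridDim)
    m[, , zRange] <- TRUE
    m
  }
  nz <- gridDim[3]
  q <- nz %/% 4
  Dproj <- c(0.4e-3 + dxBoost, 0.4e-3, 1.4e-3, 0, 0, 0)
  Dassoc <- c(0.4e-3 + dxBoost, 1.4e-3, 0.4e-3, 0, 0, 0)
  regions <- list(
    list(name = "projection", type = "tensor", mask = slab(1:q), D = Dproj),
    list(name = "association", type = "tensor", mask = slab((q + 1):(2 * q)),
         D = Dassoc),
    list(name = "smt", type = "smt", mask = slab((2 * q + 1):(3 * q)),
         v = v, lambda = lambda, nFibreDirs = nFibreDirs),
    list(name = "csf", type = "csf", mask = slab((3 * q + 1):nz),
         dIso = 3.0e-3))
  spec <- phantomSpec(gridDim, regions = regions, snr = snr, seed = seed)
  half <- gridDim[1] %/% 2
  side <- function(mask, left) {
    m <- mask
    if (left) m[(half + 1):gridDim[1], , ] <- FALSE
    else m[1:half, , ] <- FALSE
    m
  }
  rois <- fibreROISet(side(regions[[1]]$mask, TRUE),
                      side(regions[[2]]$mask, TRUE),
                      side(regions[[1]]$mask, FALSE),
                      side(regions[[2]]$mask, FALSE),
                      voxelVolume = spec$voxelSize^3)
  expectedIndex <- ((Dproj[1] + Dassoc[1]) / 2) / ((Dproj[2] + Dassoc[3]) / 2)
  list(spec = spec, rois = rois, expectedIndex = expectedIndex)
}

#' ALPS phantom with an analytically known target index
#'
#' Projection regions carry head-foot (z) oriented tensors, association
#' regions anterior-posterior (y) oriented tensors; \code{dxBoost} raises
#' Dxx of both, modelling the left-right perivascular diffusivity
#' contribution. The expected index follows by composing the index formula
#' on the generator tensors.
#'
#' @param dxBoost perivascular Dxx boost in mm^2/s (>= 0)
#' @param Dproj,Dassoc base diagonal tensors (length-3 diagonals, mm^2/s)
#' @param snr,seed,gridDim as in [defaultPhantomSpec()]
#' @return list with \code{phantom} (from [makePhantom()]), \code{rois},
#'   and \code{expectedIndex}
#' @export
makeALPSPhantom <- function(dxBoost = 0.4e-3,
                            Dproj = c(0.4, 0.4, 1.4) * 1e-3,
                            Dassoc = c(0.4, 1.4, 0.4) * 1e-3,
                            snr = Inf, seed = 1,
                            gridDim = c(20L, 20L, 12L)) {
  stopifnot(dxBoost >= 0)
  ps <- defaultPhantomSpec(snr = snr, seed = seed, gridDim = gridDim,
                           dxBoost = 0)
  ps$spec$regions[[1]]$D <- c(Dproj[1] + dxBoost, Dproj[2], Dproj[3], 0, 0, 0)
  ps$spec$regions[[2]]$D <- c(Dassoc[1] + dxBoost, Dassoc[2], Dassoc[3],
                              0, 0, 0)
  expected <- ((Dproj[1] + dxBoost + Dassoc[1] + dxBoost) / 2) /
    ((Dproj[2] + Dassoc[3]) / 2)
  list(phantom = makePhantom(ps$spec), rois = ps$rois,
       expectedIndex = expected)
}

#' Specify a synthetic cohort
#'
#' Covariate distributions default to the study cohort's descriptives:
#' age 28.7 +/- 3.7 years in \[22, 37\]; BMI 26.5 +/- 5.23 kg/m^2; systolic
#' blood pressure 123.5 +/- 13.8 mmHg; PSQI 4.85 +/- 2.80 (rounded, >= 0);
#' CFTC 113.6 +/- 20.19; usual awakening 07:04 +/- 2:04; acquisition
#' 12:04 +/- 3:19; sleep 6.80 +/- 1.15 h. Covariates are drawn
#' independently. Each outcome is a unit-variance standardized composite:
#' sum of beta * z(predictor) plus normal residual of variance
#' 1 - sum(beta^2).
#'
#' @param n number of subjects (>= 10; default 916)
#' @param effects named list: outcome -> named numeric vector of true
#'   standardized betas keyed by predictor column
#' @param regionalMeasure prefix for the 34 regional outcome columns
#'   (default "exmd"; columns \code{exmd_<region>})
#' @param seed RNG seed
#' @param pFemale probability of female sex (default 492/916)
#' @return a cohort spec list
#' @export
cohortSpec <- function(n = 916, effects = defaultCohortEffects(),
                       regionalMeasure = "exmd", seed = 1,
                       pFemale = 492 / 916) {
  stopifnot(n >= 10)
  for (out in names(effects))
    if (sum(effects[[out]]^2) >= 1)
      stop(sprintf("spec error: sum of squared betas >= 1 for outcome '%s'",
                   out))
  list(n = as.integer(n), effects = effects,
       regionalMeasure = regionalMeasure, seed = seed, pFemale = pFemale)
}

#' Default true-effect map mirroring the study's headline associations
#'
#' DTI-ALPS index: circadian time -0.07, white-matter volume -0.198,
#' male sex -0.101; white-matter FA: circadian time +0.07; grey-matter
#' INVF: PSQI +0.074, CFTC +0.149; regional exMD: medial orbitofrontal
#' -0.132 and lateral orbitofrontal -0.113 against circadian time.
#'
#' @return named list of named numeric vectors
#' @export
defaultCohortEffects <- function() {
  list(
    alps_index = c(circadian_time = -0.07, wm_volume = -0.198,
                   sex = -0.101),
    wm_fa = c(circadian_time = 0.07),
    gm_invf = c(psqi_global = 0.074, cftc = 0.149),
    gm_exmd = c(),
    exmd_medialorbitofrontal = c(circadian_time = -0.132),
    exmd_lateralorbitofrontal = c(circadian_time = -0.113))
}

clockString <- function(hours) {
  hours <- ((hours %% 24) + 24) %% 24
  h <- floor(hours)
  m <- round((hours - h) * 60)
  h <- ifelse(m == 60, h + 1, h) %% 24
  m <- ifelse(m == 60, 0, m)
  sprintf("%02d:%02d", as.integer(h), as.integer(m))
}

# Distribute a PSQI global score over the 7 components, each capped at 3:
# one point at a time to a random component with remaining capacity.
distributePSQI <- function(global) {
  comp <- integer(7)
  for (i in seq_len(global)) {
    open <- which(comp < 3L)
    if (!length(open)) break
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    comp[pick] <- comp[pick] + 1L
  }
  comp
}

#' Generate a synthetic cohort table with known standardized effects
#'
#' @param spec a [cohortSpec()] list
#' @return list with \code{table} (data.frame, one row per subject) and
#'   \code{truth} (the effect map, seed and n)
#' @export
makeCohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  d <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = ifelse(runif(n) < spec$pFemale, "female", "male"),
    age = rtruncnorm(n, 28.7, 3.7, 22, 37),
    bmi = rtruncnorm(n, 26.5, 5.23, 16.7, 47.8),
    sbp = rtruncnorm(n, 123.5, 13.8, 87, 185),
    wm_volume = rtruncnorm(n, 470000, 50000, 250000, 750000),
    stringsAsFactors = FALSE)
  d$usual_awakening <- clockString(rtruncnorm(n, 7 + 4 / 60, 2 + 4 / 60,
                                              0.5, 23.5))
  d$mid_scan <- clockString(rtruncnorm(n, 12 + 4 / 60, 3 + 19 / 60,
                                       0.5, 23.5))
  d$circadian_time <- circadianTime(d$usual_awakening, d$mid_scan)
  d$psqi_global <- pmin(21L, pmax(0L, as.integer(round(rnorm(n, 4.85,
                                                             2.80)))))
  comp <- t(vapply(d$psqi_global, distributePSQI, integer(7)))
  colnames(comp) <- paste0("psqi_c", 1:7)
  d <- cbind(d, as.data.frame(comp))
  d$sleep_duration <- rtruncnorm(n, 6.80, 1.15, 2.5, 11)
  d$cftc <- rtruncnorm(n, 113.6, 20.19, 59.34, 153.4)

  zcol <- function(nm) {
    x <- if (nm == "sex") codeSex(d[[nm]]) else as.numeric(d[[nm]])
    (x - mean(x)) / sd(x)
  }
  outcomes <- unique(c("alps_index", "wm_fa", "gm_invf", "gm_exmd",
                       paste0(spec$regionalMeasure, "_", dkRegionNames()),
                       names(spec$effects)))
  for (out in outcomes) {
    beta <- spec$effects[[out]]
    y <- rnorm(n, 0, sqrt(1 - sum(beta^2)))
    for (pred in names(beta)) y <- y + beta[[pred]] * zcol(pred)
    d[[out]] <- y
  }
  list(table = d, truth = list(effects = spec$effects, n = n,
                               seed = spec$seed))
}
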