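#' @import methods
NULL

#' Gradient table for a multi-shell diffusion acquisition
#'
#' Holds one b-value (s/mm^2) and one gradient direction per acquired volume,
#' in the FSL bvec convention (directions in the image axis frame). Directions
#' of diffusion-weighted volumes are unit vectors; b=0 volumes may carry a
#' zero direction.
#'
#' @slot bvals numeric vector of b-values in s/mm^2, one per volume.
#' @slot bvecs 3 x N numeric matrix of gradient directions, one column per
#'   volume; unit norm wherever the b-value exceeds \code{b0Threshold}.
#' @slot b0Threshold b-values at or below this (s/mm^2) are treated as b=0.
#' @slot shellTolerance maximal distance (s/mm^2) of a member b-value from
#'   its shell's nominal b.
#'
#' @seealso [gradientTable()], [groupShells()]
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix",
                 b0Threshold = "numeric", shellTolerance = "numeric"))

setValidity("GradientTable", function(object) {
  msg <- character()
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L)
    msg <- c(msg, "bvecs must be a 3 x N numeric matrix")
  else if (length(object@bvals) != ncol(object@bvecs))
    msg <- c(msg, sprintf("length(bvals) [%d] != ncol(bvecs) [%d]",
                          length(object@bvals), ncol(object@bvecs)))
  if (any(object@bvals < 0)) msg <- c(msg, "b-values must be non-negative")
  if (length(object@bvals) == ncol(object@bvecs)) {
    dw <- object@bvals > object@b0Threshold
    if (any(dw)) {
      nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-4))
        msg <- c(msg, "diffusion-weighted gradient directions must be unit vectors")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A 4-D diffusion-weighted image with its gradient table
#'
#' @slot signal 4-D non-negative array (x, y, z, volume).
#' @slot affine 4 x 4 voxel-to-world transform.
#' @slot gradients a [GradientTable-class] with one entry per volume.
#' @export
setClass("DWIVolume",
  representation(signal = "array", affine = "matrix",
                 gradients = "GradientTable"))

setValidity("DWIVolume", function(object) {
  msg <- character()
  if (length(dim(object@signal)) != 4L)
    msg <- c(msg, "signal must be a 4-D array")
  else if (dim(object@signal)[4] != length(object@gradients@bvals))
    msg <- c(msg, sprintf(
      "protocol error: %d image volumes but %d gradient entries",
      dim(object@signal)[4], length(object@gradients@bvals)))
  if (any(object@signal < 0, na.rm = TRUE))
    msg <- c(msg, "signal values must be non-negative")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4 x 4")
  if (length(msg)) msg else TRUE
})

#' Partition of acquisition volumes into b=0 set and shells
#'
#' @slot b0Indices integer indices of volumes at or below the b0 threshold.
#' @slot shells list of \code{list(b = nominal b, indices = volume indices)},
#'   nominal b being the member mean rounded to the nearest 10 s/mm^2.
#' @export
setClass("ShellGrouping",
  representation(b0Indices = "integer", shells = "list"))

#' Per-voxel symmetric diffusion tensor field
#'
#' Tensor elements are stored in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#' units mm^2/s, in the image axis frame.
#'
#' @slot D 4-D array (x, y, z, 6) of tensor elements.
#' @slot logS0 3-D array of fitted log S0.
#' @slot affine 4 x 4 voxel-to-world transform.
#' @slot fitMask logical 3-D array; TRUE where a tensor was fitted.
#' @export
setClass("TensorField",
  representation(D = "array", logS0 = "array", affine = "matrix",
                 fitMask = "array"))

setValidity("TensorField", function(object) {
  msg <- character()
  if (length(dim(object@D)) != 4L || dim(object@D)[4] != 6L)
    msg <- c(msg, "D must be an (x, y, z, 6) array")
  if (!identical(dim(object@fitMask), dim(object@D)[1:3]))
    msg <- c(msg, "fitMask must match the spatial grid of D")
  if (length(msg)) msg else TRUE
})

#' A 3-D scalar map with a declared meaning
#'
#' @slot values 3-D numeric array (NA/NaN where undefined).
#' @slot affine 4 x 4 voxel-to-world transform.
#' @slot meaning one of "FA", "MD", "INVF", "exMD", "lambda", "other".
#' @export
setClass("ScalarMap",
  representation(values = "array", affine = "matrix", meaning = "character"))

setValidity("ScalarMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  v <- object@values[is.finite(object@values)]
  if (object@meaning %in% c("FA", "INVF") && length(v) &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, sprintf("%s values must lie in [0, 1]", object@meaning))
  if (object@meaning %in% c("MD", "exMD") && length(v) && min(v) < -1e-12)
    msg <- c(msg, sprintf("%s values must be non-negative", object@meaning))
  if (length(msg)) msg else TRUE
})

#' Projection- and association-fibre ROI masks for the ALPS index
#'
#' Boolean masks in image space, per hemisphere. Within a hemisphere the
#' projection and association masks must be disjoint and non-empty.
#'
#' @slot leftProjection,leftAssociation,rightProjection,rightAssociation
#'   logical 3-D arrays.
#' @slot voxelVolume voxel volume in mm^3.
#' @export
setClass("FibreROISet",
  representation(leftProjection = "array", leftAssociation = "array",
                 rightProjection = "array", rightAssociation = "array",
                 voxelVolume = "numeric"))

setValidity("FibreROISet", function(object) {
  msg <- character()
  for (h in c("left", "right")) {
    p <- slot(object, paste0(h, "Projection"))
    a <- slot(object, paste0(h, "Association"))
    if (!identical(dim(p), dim(a)))
      msg <- c(msg, sprintf("%s hemisphere masks differ in shape", h))
    else {
      if (any(p & a))
        msg <- c(msg, sprintf("%s projection and association masks overlap", h))
      if (!any(p) || !any(a))
        msg <- c(msg, sprintf("%s hemisphere has an empty mask", h))
    }
  }
  if (object@voxelVolume <= 0) msg <- c(msg, "voxelVolume must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of the DTI-ALPS computation
#'
#' @slot hemispheres data.frame with one row per hemisphere: the four
#'   ROI-averaged diffusivities (mm^2/s), ROI sizes (mm^3) and the
#'   per-hemisphere index.
#' @slot index arithmetic mean of the left and right indices.
#' @export
setClass("ALPSResult",
  representation(hemispheres = "data.frame", index = "numeric"))

#' Per-voxel spherical-mean signal profile
#'
#' Normalized per-shell direction-averaged signals e(b) = mean shell signal /
#' mean b0 signal. Shell b-values are carried in ms/um^2 (1000 s/mm^2 =
#' 1 ms/um^2) so that b * diffusivity is O(1).
#'
#' @slot means 4-D array (x, y, z, shell) of normalized mean signals.
#' @slot shellB numeric vector of nominal shell b-values in ms/um^2.
#' @slot clipped logical 3-D array; TRUE where a shell mean was clipped.
#' @slot excluded logical 3-D array; TRUE where the voxel was dropped
#'   (zero mean b0).
#' @slot affine 4 x 4 voxel-to-world transform.
#' @export
setClass("SphericalMeanProfile",
  representation(means = "array", shellB = "numeric", clipped = "array",
                 excluded = "array", affine = "matrix"))

#' Per-voxel two-compartment spherical-mean fit
#'
#' @slot v 3-D array, intra-neurite volume fraction in [0, 1].
#' @slot lambda 3-D array, intrinsic diffusivity in um^2/ms.
#' @slot exmd 3-D array, extra-neurite mean diffusivity lambda*(3-2v)/3
#'   in um^2/ms.
#' @slot rss 3-D array, residual sum of squares over shells.
#' @slot converged logical 3-D array.
#' @slot flags logical 3-D array; TRUE where the fit was skipped.
#' @slot affine 4 x 4 voxel-to-world transform.
#' @export
setClass("SMTFit",
  representation(v = "array", lambda = "array", exmd = "array",
                 rss = "array", converged = "array", flags = "array",
                 affine = "matrix"))

#' Integer label volume with a region dictionary
#'
#' @slot labels 3-D integer array; 0 is background.
#' @slot affine 4 x 4 voxel-to-world transform.
#' @slot dictionary named character vector mapping label (as name) to
#'   region name.
#' @slot greyLabels,whiteLabels integer label subsets defining the pooled
#'   grey- and white-matter composites.
#' @export
setClass("LabelVolume",
  representation(labels = "array", affine = "matrix",
                 dictionary = "character",
                 greyLabels = "integer", whiteLabels = "integer"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  present <- setdiff(unique(as.integer(object@labels)), 0L)
  missing <- setdiff(present, as.integer(names(object@dictionary)))
  if (length(missing))
    msg <- c(msg, sprintf("labels without dictionary entry: %s",
                          paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
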