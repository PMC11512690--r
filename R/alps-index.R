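#' @include AllClasses.R tensor-model.R
NULL

#' Construct a fibre-ROI set for the ALPS index
#'
#' @param leftProjection,leftAssociation,rightProjection,rightAssociation
#'   logical 3-D arrays in image space (projection fibres run head-foot,
#'   association fibres anterior-posterior, both perpendicular to the
#'   left-right perivascular direction)
#' @param voxelVolume voxel volume in mm^3
#' @return a [FibreROISet-class]
#' @export
fibreROISet <- function(leftProjection, leftAssociation,
                        rightProjection, rightAssociation,
                        voxelVolume = 1) {
  new("FibreROISet",
      leftProjection = leftProjection, leftAssociation = leftAssociation,
      rightProjection = rightProjection, rightAssociation = rightAssociation,
      voxelVolume = voxelVolume)
}

#' Load a fibre-ROI set from NIfTI label/mask files
#'
#' @param leftProjection,leftAssociation,rightProjection,rightAssociation
#'   paths to binary masks in image space
#' @param voxelVolume voxel volume in mm^3; if NULL, derived from the first
#'   mask's affine (product of axis scales)
#' @return a [FibreROISet-class]
#' @export
loadFibreROISet <- function(leftProjection, leftAssociation,
                            rightProjection, rightAssociation,
                            voxelVolume = NULL) {
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    list(mask = asPlainArray(img) > 0, affine = unclass(RNifti::xform(img)))
  }
  lp <- rd(leftProjection); la <- rd(leftAssociation)
  rp <- rd(rightProjection); ra <- rd(rightAssociation)
  if (is.null(voxelVolume)) {
    R <- lp$affine[1:3, 1:3]
    voxelVolume <- prod(sqrt(colSums(R^2)))
  }
  fibreROISet(lp$mask, la$mask, rp$mask, ra$mask, voxelVolume)
}

#' ROI-averaged axis diffusivities for the ALPS index
#'
#' For each hemisphere, averages Dxx over the projection mask (D_xproj) and
#' the association mask (D_xassoc), Dyy over the projection mask (D_yproj)
#' and Dzz over the association mask (D_zassoc). Voxels whose stored tensor
#' is identically zero (no fit output) are excluded from the means.
#'
#' @param t a [TensorField-class]
#' @param rois a [FibreROISet-class] on the same grid
#' @return data.frame with one row per hemisphere: Dxproj, Dxassoc, Dyproj,
#'   Dzassoc (mm^2/s) and ROI sizes (mm^3, non-zero voxels only)
#' @export
roiMeanDiffusivities <- function(t, rois) {
  stopifnot(is(t, "TensorField"), is(rois, "FibreROISet"))
  dims <- dim(t@D)[1:3]
  if (!identical(dim(rois@leftProjection), dims))
    stop("grid error: ROI masks and tensor field differ in shape")
  n <- prod(dims)
  Dflat <- matrix(t@D, n, 6L)
  nonZero <- rowSums(Dflat != 0) > 0
  one <- function(hemi) {
    proj <- as.vector(slot(rois, paste0(hemi, "Projection"))) & nonZero
    assoc <- as.vector(slot(rois, paste0(hemi, "Association"))) & nonZero
    if (!any(proj))
      stop(sprintf("ALPS error: %s projection mask has no non-zero voxels",
                   hemi))
    if (!any(assoc))
      stop(sprintf("ALPS error: %s association mask has no non-zero voxels",
                   hemi))
    data.frame(hemisphere = hemi,
               Dxproj = mean(Dflat[proj, 1]),
               Dxassoc = mean(Dflat[assoc, 1]),
               Dyproj = mean(Dflat[proj, 2]),
               Dzassoc = mean(Dflat[assoc, 3]),
               projSize = sum(proj) * rois@voxelVolume,
               assocSize = sum(assoc) * rois@voxelVolume)
  }
  rbind(one("left"), one("right"))
}

#' DTI-ALPS index from per-hemisphere diffusivity quadruples
#'
#' Per hemisphere:
#' index = mean(D_xproj, D_xassoc) / mean(D_yproj, D_zassoc),
#' i.e. diffusivity along the left-right perivascular axis over diffusivity
#' perpendicular to both fibre populations and the vessels. The indices of
#' the two hemispheres are computed independently and their arithmetic mean
#' reported. An index of 1 means no preferential perivascular diffusion.
#'
#' @param d data.frame as returned by [roiMeanDiffusivities()] (columns
#'   hemisphere, Dxproj, Dxassoc, Dyproj, Dzassoc, optional sizes)
#' @return an [ALPSResult-class]
#' @export
alpsIndex <- function(d) {
  need <- c("Dxproj", "Dxassoc", "Dyproj", "Dzassoc")
  stopifnot(all(need %in% names(d)))
  if (any(!is.finite(as.matrix(d[need]))))
    stop("ALPS error: non-finite diffusivity")
  denom <- (d$Dyproj + d$Dzassoc) / 2
  if (any(denom <= 0))
    stop("ALPS error: non-positive perpendicular diffusivity")
  d$index <- ((d$Dxproj + d$Dxassoc) / 2) / denom
  new("ALPSResult", hemispheres = d, index = mean(d$index))
}

#' Full ALPS computation from a tensor field and ROI set
#'
#' @inheritParams roiMeanDiffusivities
#' @return an [ALPSResult-class]
#' @export
computeALPS <- function(t, rois) {
  alpsIndex(roiMeanDiffusivities(t, rois))
}

#' Serialize an ALPS result to JSON
#'
#' @param res an [ALPSResult-class]
#' @param path output JSON path
#' @return the path, invisibly
#' @export
writeALPSResult <- function(res, path) {
  stopifnot(is(res, "ALPSResult"))
  h <- res@hemispheres
  out <- lapply(seq_len(nrow(h)), function(i) as.list(h[i, -1]))
  names(out) <- h$hemisphere
  out$mean_index <- res@index
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
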