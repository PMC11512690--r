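#' @include AllClasses.R AllGenerics.R
NULL

# Plain numeric array from a niftiImage (drops RNifti attributes/class).
asPlainArray <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

#' Construct a gradient table
#'
#' Directions with non-zero norm are renormalized to unit length (the FSL
#' dialect allows arbitrarily scaled bvec columns); zero columns (typical for
#' b=0 volumes) are kept as-is.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x N matrix (or N x 3, auto-transposed) of directions.
#' @param b0Threshold b-values at or below this are treated as b=0
#'   (default 50 s/mm^2; HCP effective b-values jitter around the nominals).
#' @param shellTolerance shell membership tolerance (default 100 s/mm^2).
#' @return a [GradientTable-class]
#' @examples
#' gt <- gradientTable(c(0, 1000, 1000), cbind(0, c(2, 0, 0), c(0, 1, 0)))
#' bVectors(gt)[, 2]  # renormalized to unit length
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50,
                          shellTolerance = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (FSL dialect: 3 rows x N columns)")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("protocol error: %d b-values but %d gradient directions",
                 length(bvals), ncol(bvecs)))
  nrm <- sqrt(colSums(bvecs^2))
  nz <- nrm > 0
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm[nz], "/")
  new("GradientTable", bvals = bvals, bvecs = bvecs,
      b0Threshold = b0Threshold, shellTolerance = shellTolerance)
}

#' Load a 4-D DWI volume with FSL-dialect bval/bvec files
#'
#' @param imagePath NIfTI-1 image path (.nii or .nii.gz).
#' @param bvalPath whitespace-delimited b-value file (1 x N).
#' @param bvecPath whitespace-delimited direction file (3 rows x N columns).
#' @param b0Threshold,shellTolerance passed to [gradientTable()].
#' @param maxObliquity maximal allowed deviation (degrees) of each image
#'   axis from the corresponding world axis; the ALPS index reads tensor
#'   elements by axis, so grossly oblique acquisitions are rejected.
#'   Set to \code{Inf} to disable the check.
#' @return a [DWIVolume-class]
#' @export
loadDWI <- function(imagePath, bvalPath, bvecPath, b0Threshold = 50,
                    shellTolerance = 100, maxObliquity = 20) {
  for (p in c(imagePath, bvalPath, bvecPath))
    if (!file.exists(p)) stop(sprintf("cannot read '%s': no such file", p))
  img <- RNifti::readNifti(imagePath)
  sig <- asPlainArray(img)
  if (length(dim(sig)) == 3L) dim(sig) <- c(dim(sig), 1L)
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecRows <- utils::read.table(bvecPath)
  bvecs <- as.matrix(bvecRows)
  gt <- gradientTable(bvals, bvecs, b0Threshold, shellTolerance)
  if (dim(sig)[4] != length(bvals))
    stop(sprintf("protocol error: image has %d volumes but %d gradient entries",
                 dim(sig)[4], length(bvals)))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  checkObliquity(affine, maxObliquity)
  new("DWIVolume", signal = sig, affine = affine, gradients = gt)
}

# Angle (degrees) between each normalized affine column and its world axis;
# errors above the threshold. NIfTI xforms are commonly x-flipped (RAS vs
# LAS), so axes are compared up to sign.
checkObliquity <- function(affine, maxObliquity = 20) {
  if (!is.finite(maxObliquity)) return(invisible(TRUE))
  R <- affine[1:3, 1:3]
  for (i in 1:3) {
    col <- R[, i] / sqrt(sum(R[, i]^2))
    ang <- acos(min(1, abs(col[i]))) * 180 / pi
    if (ang > maxObliquity)
      stop(sprintf(
        "image axis %d deviates %.1f degrees from the world axis (limit %g); the ALPS convention requires near axis-aligned acquisitions",
        i, ang, maxObliquity))
  }
  invisible(TRUE)
}

#' @describeIn groupShells shell grouping of a gradient table
#' @examples
#' gt <- gradientTable(c(0, 5, 995, 1005, 2000),
#'                     matrix(c(0, 0, 0,  0, 0, 0,  1, 0, 0,  1, 0, 0,
#'                              0, 1, 0), nrow = 3))
#' groupShells(gt)
setMethod("groupShells", "GradientTable", function(x) {
  if (length(x@bvals) == 0L) stop("protocol error: empty gradient table")
  b0 <- which(x@bvals <= x@b0Threshold)
  shells <- list()  # each: list(sum, n, indices)
  for (i in setdiff(seq_along(x@bvals), b0)) {
    b <- x@bvals[i]
    placed <- FALSE
    for (k in seq_along(shells)) {
      if (abs(b - shells[[k]]$sum / shells[[k]]$n) <= x@shellTolerance) {
        shells[[k]]$sum <- shells[[k]]$sum + b
        shells[[k]]$n <- shells[[k]]$n + 1L
        shells[[k]]$indices <- c(shells[[k]]$indices, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) shells[[length(shells) + 1L]] <- list(sum = b, n = 1L,
                                                      indices = i)
  }
  shells <- lapply(shells, function(s)
    list(b = round(s$sum / s$n / 10) * 10, indices = as.integer(s$indices)))
  shells <- shells[order(vapply(shells, `[[`, 0, "b"))]
  new("ShellGrouping", b0Indices = as.integer(b0), shells = shells)
})

#' @describeIn groupShells shell grouping of a DWI volume's gradients
setMethod("groupShells", "DWIVolume", function(x) groupShells(x@gradients))

#' Write a scalar map as NIfTI-1 (32-bit float)
#'
#' NA/NaN voxels (e.g. outside the fit mask) are permitted and stored as
#' NaN; infinite values are rejected.
#'
#' @param map a [ScalarMap-class]
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
saveScalarMap <- function(map, path) {
  stopifnot(is(map, "ScalarMap"))
  bad <- sum(is.infinite(map@values))
  if (bad > 0)
    stop(sprintf("validation error: %d non-finite (infinite) voxels", bad))
  img <- RNifti::asNifti(map@values)
  RNifti::sform(img) <- structure(map@affine, code = 2L)
  RNifti::qform(img) <- structure(map@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a scalar map written by [saveScalarMap()] (or any 3-D NIfTI)
#'
#' @param path NIfTI-1 path
#' @param meaning meaning tag to attach (default "other")
#' @return a [ScalarMap-class]
#' @export
loadScalarMap <- function(path, meaning = "other") {
  img <- RNifti::readNifti(path)
  vals <- asPlainArray(img)
  if (length(dim(vals)) != 3L) stop("expected a 3-D scalar volume")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  new("ScalarMap", values = vals, affine = affine, meaning = meaning)
}

#' Write a DWI volume plus FSL-dialect gradient files
#'
#' @param dwi a [DWIVolume-class]
#' @param imagePath,bvalPath,bvecPath output paths
#' @return imagePath, invisibly
#' @export
saveDWI <- function(dwi, imagePath, bvalPath, bvecPath) {
  stopifnot(is(dwi, "DWIVolume"))
  img <- RNifti::asNifti(dwi@signal)
  RNifti::sform(img) <- structure(dwi@affine, code = 2L)
  RNifti::qform(img) <- structure(dwi@affine, code = 2L)
  RNifti::writeNifti(img, imagePath, datatype = "float")
  writeLines(paste(format(dwi@gradients@bvals, scientific = FALSE,
                          trim = TRUE), collapse = " "), bvalPath)
  write.table(format(dwi@gradients@bvecs, digits = 17, scientific = FALSE,
                     trim = TRUE),
              bvecPath, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(imagePath)
}

#' Write a tensor field as a 6-volume NIfTI with a JSON sidecar
#'
#' Element order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) is recorded in the sidecar.
#'
#' @param t a [TensorField-class]
#' @param path output NIfTI path; the sidecar is written next to it
#' @return the path, invisibly
#' @export
saveTensorField <- function(t, path) {
  stopifnot(is(t, "TensorField"))
  img <- RNifti::asNifti(t@D)
  RNifti::sform(img) <- structure(t@affine, code = 2L)
  RNifti::qform(img) <- structure(t@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(element_order = c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"),
         units = "mm^2/s"),
    side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
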