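#' @include AllClasses.R
NULL

#' b-values of a gradient table or DWI volume
#' @param x a [GradientTable-class] or [DWIVolume-class]
#' @return numeric vector of b-values in s/mm^2
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Gradient directions (3 x N matrix, FSL bvec convention)
#' @param x a [GradientTable-class] or [DWIVolume-class]
#' @return 3 x N numeric matrix
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' Number of acquisition volumes
#' @param x a [GradientTable-class] or [DWIVolume-class]
#' @return integer count
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' Voxel-to-world affine of an image-space object
#' @param x an object carrying an affine slot
#' @return 4 x 4 matrix
#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' Group acquisition volumes into a b=0 set and shells
#'
#' Volumes with b-value at or below the table's b0 threshold form the b=0
#' set. The remaining volumes are partitioned greedily: a b-value joins the
#' first shell whose running nominal b it is within the shell tolerance of,
#' otherwise it seeds a new shell. Each shell's nominal b is the mean of its
#' member b-values rounded to the nearest 10 s/mm^2.
#'
#' @param x a [GradientTable-class] or [DWIVolume-class]
#' @return a [ShellGrouping-class]
#' @export
setGeneric("groupShells", function(x) standardGeneric("groupShells"))

#' @describeIn bValues b-values of a gradient table
setMethod("bValues", "GradientTable", function(x) x@bvals)
#' @describeIn bValues b-values of a DWI volume
setMethod("bValues", "DWIVolume", function(x) x@gradients@bvals)
#' @describeIn bVectors directions of a gradient table
setMethod("bVectors", "GradientTable", function(x) x@bvecs)
#' @describeIn bVectors directions of a DWI volume
setMethod("bVectors", "DWIVolume", function(x) x@gradients@bvecs)
#' @describeIn nVolumes volume count of a gradient table
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))
#' @describeIn nVolumes volume count of a DWI volume
setMethod("nVolumes", "DWIVolume", function(x) dim(x@signal)[4])
#' @describeIn imageAffine affine of a DWI volume
setMethod("imageAffine", "DWIVolume", function(x) x@affine)
#' @describeIn imageAffine affine of a tensor field
setMethod("imageAffine", "TensorField", function(x) x@affine)
#' @describeIn imageAffine affine of a scalar map
setMethod("imageAffine", "ScalarMap", function(x) x@affine)

#' Values of a scalar map
#' @param x a [ScalarMap-class]
#' @return 3-D numeric array
#' @export
mapValues <- function(x) {
  stopifnot(is(x, "ScalarMap"))
  x@values
}

#' Meaning tag of a scalar map ("FA", "MD", "INVF", "exMD", ...)
#' @param x a [ScalarMap-class]
#' @return character scalar
#' @export
mapMeaning <- function(x) {
  stopifnot(is(x, "ScalarMap"))
  x@meaning
}

#' Per-hemisphere table of an ALPS result
#' @param x an [ALPSResult-class]
#' @return data.frame with one row per hemisphere
#' @export
alpsHemispheres <- function(x) {
  stopifnot(is(x, "ALPSResult"))
  x@hemispheres
}

#' Mean DTI-ALPS index of an ALPS result
#' @param x an [ALPSResult-class]
#' @return numeric scalar
#' @export
alpsMeanIndex <- function(x) {
  stopifnot(is(x, "ALPSResult"))
  x@index
}

setMethod("show", "GradientTable", function(object) {
  g <- groupShells(object)
  cat(sprintf("GradientTable: %d volumes (%d b0, shells: %s)\n",
              length(object@bvals), length(g@b0Indices),
              if (length(g@shells))
                paste(vapply(g@shells, function(s)
                  sprintf("b=%g n=%d", s$b, length(s$indices)), ""),
                  collapse = ", ")
              else "none"))
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DWIVolume: %d x %d x %d grid, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  show(object@gradients)
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@D)
  cat(sprintf("TensorField: %d x %d x %d grid, %d voxels fitted\n",
              d[1], d[2], d[3], sum(object@fitMask)))
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("ScalarMap [%s]: %s grid, finite range [%g, %g]\n",
              object@meaning, paste(dim(object@values), collapse = " x "),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ALPSResult", function(object) {
  cat("ALPSResult\n")
  print(object@hemispheres, digits = 5)
  cat(sprintf("mean DTI-ALPS index: %.5f\n", object@index))
})

setMethod("show", "SMTFit", function(object) {
  ok <- !object@flags
  cat(sprintf("SMTFit: %s grid, %d voxels fitted, median v = %.3f, median lambda = %.3f um^2/ms\n",
              paste(dim(object@v), collapse = " x "), sum(ok),
              stats::median(object@v[ok]), stats::median(object@lambda[ok])))
})

setMethod("show", "ShellGrouping", function(object) {
  cat(sprintf("ShellGrouping: %d b0 volumes, %d shells\n",
              length(object@b0Indices), length(object@shells)))
  for (s in object@shells)
    cat(sprintf("  b = %g s/mm^2: %d directions\n", s$b, length(s$indices)))
})
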