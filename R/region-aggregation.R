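#' @include AllClasses.R
NULL

#' The 34 Desikan-Killiany cortical region names
#'
#' Bilateral labels are pooled per region (34 regions, not 68).
#'
#' @return character vector of length 34
#' @export
dkRegionNames <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
}

#' Construct a label volume
#'
#' @param labels 3-D integer array (0 = background)
#' @param dictionary named character vector: label (as name) -> region name
#' @param greyLabels,whiteLabels label subsets pooled into the
#'   "grey_matter" / "white_matter" composites
#' @param affine 4 x 4 voxel-to-world transform
#' @return a [LabelVolume-class]
#' @export
labelVolume <- function(labels, dictionary, greyLabels = integer(),
                        whiteLabels = integer(), affine = diag(4)) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, affine = affine,
      dictionary = dictionary, greyLabels = as.integer(greyLabels),
      whiteLabels = as.integer(whiteLabels))
}

#' Load a label volume from NIfTI + JSON dictionary
#'
#' The JSON dictionary maps label numbers to region names and may carry
#' \code{grey_labels} / \code{white_labels} arrays:
#' \code{{"regions": {"1": "bankssts", ...}, "grey_labels": [...],
#' "white_labels": [...]}}.
#'
#' @param imagePath NIfTI label volume
#' @param dictPath JSON dictionary path
#' @return a [LabelVolume-class]
#' @export
loadLabelVolume <- function(imagePath, dictPath) {
  img <- RNifti::readNifti(imagePath)
  dict <- jsonlite::read_json(dictPath, simplifyVector = TRUE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  labelVolume(asPlainArray(img), unlist(dict$regions),
              dict$grey_labels %||% integer(),
              dict$white_labels %||% integer(), affine)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regional means of a scalar map over an atlas
#'
#' Per label, the mean over that label's voxels, excluding NaN map values
#' and any voxel in \code{exclude}. The composite rows "grey_matter" and
#' "white_matter" are voxel-weighted means over the pooled grey / white
#' label sets (i.e. the composite ROI is treated as a single region, not an
#' average of region means). Labels whose voxels are all excluded are
#' omitted with a warning.
#'
#' @param map a [ScalarMap-class]
#' @param atlas a [LabelVolume-class] on the same grid
#' @param exclude optional logical 3-D exclusion mask
#' @return data.frame with columns region, mean, n
#' @export
regionMeans <- function(map, atlas, exclude = NULL) {
  stopifnot(is(map, "ScalarMap"), is(atlas, "LabelVolume"))
  if (!identical(dim(map@values), dim(atlas@labels)))
    stop("grid error: map and atlas differ in shape")
  vals <- as.vector(map@values)
  labs <- as.vector(atlas@labels)
  ok <- is.finite(vals) & labs != 0L
  if (!is.null(exclude)) ok <- ok & !as.vector(exclude)
  rows <- list()
  for (lab in sort(unique(labs[labs != 0L]))) {
    sel <- ok & labs == lab
    name <- atlas@dictionary[[as.character(lab)]]
    if (!any(sel)) {
      warning(sprintf("label %d (%s): all voxels excluded; row omitted",
                      lab, name))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(region = name,
                                            mean = mean(vals[sel]),
                                            n = sum(sel))
  }
  comp <- function(set, name) {
    if (length(set) == 0L) return(NULL)
    sel <- ok & labs %in% set
    if (!any(sel)) {
      warning(sprintf("composite %s: all voxels excluded; row omitted", name))
      return(NULL)
    }
    data.frame(region = name, mean = mean(vals[sel]), n = sum(sel))
  }
  out <- do.call(rbind, c(rows,
                          list(comp(atlas@greyLabels, "grey_matter"),
                               comp(atlas@whiteLabels, "white_matter"))))
  rownames(out) <- NULL
  out
}

#' Merge per-subject region tables into one cohort-wide table
#'
#' @param tables named list (names = subject ids) of [regionMeans()]
#'   data.frames for one measure
#' @param measure measure name recorded in the "measure" attribute
#' @return data.frame: one row per subject, one column per region (plus
#'   composites); regions absent for a subject become NA with a message
#' @export
mergeSubjectTables <- function(tables, measure = "value") {
  ids <- names(tables)
  if (is.null(ids) || any(ids == ""))
    stop("tables must be a named list keyed by subject id")
  if (anyDuplicated(ids))
    stop(sprintf("validation error: duplicate subject identifier '%s'",
                 ids[duplicated(ids)][1]))
  regions <- unique(unlist(lapply(tables, function(t) t$region)))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (r in regions)
    out[[r]] <- vapply(tables, function(t) {
      i <- match(r, t$region)
      if (is.na(i)) NA_real_ else t$mean[i]
    }, 0)
  miss <- sum(is.na(out[regions]))
  if (miss > 0)
    message(sprintf("%d missing region cells across %d subjects", miss,
                    length(ids)))
  attr(out, "measure") <- measure
  rownames(out) <- NULL
  out
}

#' Write / read a cohort-wide region table as TSV
#'
#' UTF-8, '.' decimal, header row; full double precision.
#'
#' @param table data.frame from [mergeSubjectTables()] (or any cohort table)
#' @param path TSV path
#' @return the path (write) or the data.frame (read)
#' @export
writeRegionTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeRegionTable
#' @export
readRegionTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
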