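#' @include AllClasses.R synthetic-data.R tensor-model.R alps-index.R smt.R
#' @include region-aggregation.R cohort-statistics.R
NULL

#' Default pipeline configuration
#'
#' @param outDir output directory
#' @param seed master seed; stage seeds derive deterministically from it
#' @param stages stages to run, a subset of phantom, tensor, alps, smt,
#'   regions, cohort, stats (in dependency order)
#' @param snr phantom SNR (Inf = noise-free)
#' @param nFibreDirs fibre orientations per smt voxel (Inf = dispersed)
#' @param gridDim phantom grid
#' @param cohortN synthetic cohort size
#' @param effects true-effect map for the cohort stage
#' @param models model descriptors for the stats stage (list, or YAML path)
#' @return a config list
#' @export
pipelineConfig <- function(outDir, seed = 1,
                           stages = c("phantom", "tensor", "alps", "smt",
                                      "regions", "cohort", "stats"),
                           snr = 50, nFibreDirs = Inf,
                           gridDim = c(20L, 20L, 12L), cohortN = 916,
                           effects = defaultCohortEffects(),
                           models = defaultModelDescriptors()) {
  list(outDir = outDir, seed = seed, stages = stages, snr = snr,
       nFibreDirs = nFibreDirs, gridDim = gridDim, cohortN = cohortN,
       effects = effects, models = models)
}

#' Default model descriptors mirroring the study's main models
#'
#' @return list of descriptor lists usable by [runCohortModels()]
#' @export
defaultModelDescriptors <- function() {
  list(
    list(name = "alps_main", outcome = "alps_index",
         predictors = c("circadian_time", "wm_volume", "sex", "age",
                        "sbp", "bmi")),
    list(name = "wm_fa_circadian", outcome = "wm_fa",
         predictors = c("circadian_time", "wm_volume")),
    list(name = "gm_invf_cftc", outcome = "gm_invf",
         predictors = c("cftc", "age", "bmi", "psqi_global"),
         interactions = list(c("psqi_global", "cftc"))),
    list(name = "gm_invf_sleep_cftc", outcome = "gm_invf",
         predictors = c("cftc", "age", "bmi", "sleep_duration"),
         interactions = list(c("sleep_duration", "cftc")),
         recentre = list(sleep_duration = 8)))
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order (simulate phantom ->
#' tensor fit -> ALPS -> spherical-mean fit -> regional aggregation;
#' simulate cohort -> cohort statistics), writes every product under the
#' configured output directory, and records a JSON manifest with the seed,
#' a config hash, and an MD5 checksum of every file written. Rerunning
#' with the same config reproduces all numeric outputs byte-identically.
#'
#' @param config list from [pipelineConfig()]
#' @return the manifest list, invisibly; also written to
#'   \code{manifest.json}
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  files <- character()
  addFile <- function(p) files <<- c(files, p)
  out <- function(name) file.path(config$outDir, name)
  need <- function(stage, dep, product) {
    if (!(dep %in% stages) && !file.exists(product))
      stop(sprintf("dependency error: stage '%s' needs '%s' output (%s)",
                   stage, dep, product))
  }

  phantom <- NULL; rois <- NULL; tensor <- NULL; smtResult <- NULL

  if ("phantom" %in% stages) {
    ps <- defaultPhantomSpec(snr = config$snr,
                             nFibreDirs = config$nFibreDirs,
                             seed = config$seed, gridDim = config$gridDim)
    phantom <- makePhantom(ps$spec)
    rois <- ps$rois
    saveDWI(phantom$dwi, out("dwi.nii"), out("dwi.bval"), out("dwi.bvec"))
    addFile(out("dwi.nii")); addFile(out("dwi.bval")); addFile(out("dwi.bvec"))
    jsonlite::write_json(list(expected_alps_index = ps$expectedIndex,
                              snr = config$snr, seed = config$seed),
                         out("phantom_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    addFile(out("phantom_truth.json"))
  }

  if ("tensor" %in% stages) {
    need("tensor", "phantom", out("dwi.nii"))
    if (is.null(phantom)) {
      dwi <- loadDWI(out("dwi.nii"), out("dwi.bval"), out("dwi.bvec"))
    } else dwi <- phantom$dwi
    tensor <- fitTensor(dwi)
    saveTensorField(tensor, out("tensor.nii"))
    addFile(out("tensor.nii")); addFile(out("tensor.json"))
    eig <- tensorEigensystem(tensor)
    maps <- faMD(eig)
    saveScalarMap(maps$FA, out("fa.nii")); addFile(out("fa.nii"))
    saveScalarMap(maps$MD, out("md.nii")); addFile(out("md.nii"))
  }

  if ("alps" %in% stages) {
    if (is.null(tensor))
      stop("dependency error: stage 'alps' needs the tensor stage")
    if (is.null(rois))
      stop("dependency error: stage 'alps' needs phantom ROIs")
    res <- computeALPS(tensor, rois)
    writeALPSResult(res, out("alps.json"))
    addFile(out("alps.json"))
  }

  if ("smt" %in% stages) {
    if (is.null(phantom))
      stop("dependency error: stage 'smt' needs the phantom stage")
    smtMask <- phantom$labels == which(vapply(defaultPhantomSpec(
      seed = config$seed, gridDim = config$gridDim)$spec$regions,
      function(r) r$type, "") == "smt")[1]
    prof <- sphericalMeans(phantom$dwi, mask = smtMask)
    smtResult <- fitSMT(prof)
    m <- smtMaps(smtResult)
    saveScalarMap(m$INVF, out("smt_invf.nii")); addFile(out("smt_invf.nii"))
    saveScalarMap(m$exMD, out("smt_exmd.nii")); addFile(out("smt_exmd.nii"))
    lam <- new("ScalarMap", values = smtResult@lambda,
               affine = smtResult@affine, meaning = "other")
    saveScalarMap(lam, out("smt_lambda.nii")); addFile(out("smt_lambda.nii"))
  }

  if ("regions" %in% stages) {
    if (is.null(smtResult) || is.null(phantom))
      stop("dependency error: stage 'regions' needs the smt stage")
    regionNames <- vapply(defaultPhantomSpec(
      seed = config$seed, gridDim = config$gridDim)$spec$regions,
      `[[`, "", "name")
    smtIdx <- which(regionNames == "smt")[1]
    labs <- phantom$labels
    labs[labs != smtIdx] <- 0L  # other slabs carry no spherical-mean fit
    atlas <- labelVolume(labs, setNames(regionNames[smtIdx],
                                        as.character(smtIdx)),
                         greyLabels = smtIdx,
                         affine = imageAffine(phantom$dwi))
    m <- smtMaps(smtResult)
    tab <- regionMeans(m$INVF, atlas)
    writeRegionTable(tab, out("region_means.tsv"))
    addFile(out("region_means.tsv"))
  }

  cohort <- NULL
  if ("cohort" %in% stages) {
    cs <- cohortSpec(n = config$cohortN, effects = config$effects,
                     seed = config$seed)
    cohort <- makeCohort(cs)
    writeCohortTable(cohort$table, out("cohort.tsv"))
    addFile(out("cohort.tsv"))
    truthSerial <- cohort$truth
    truthSerial$effects <- lapply(truthSerial$effects, as.list)
    jsonlite::write_json(truthSerial, out("cohort_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    addFile(out("cohort_truth.json"))
  }

  if ("stats" %in% stages) {
    if (is.null(cohort)) {
      need("stats", "cohort", out("cohort.tsv"))
      cohort <- list(table = readCohortTable(out("cohort.tsv")))
    }
    fits <- runCohortModels(cohort$table, config$models)
    serial <- lapply(fits, function(f)
      list(descriptor = f$descriptor, n = f$n, r_squared = f$r_squared,
           terms = f$terms))
    jsonlite::write_json(serial, out("model_results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    addFile(out("model_results.json"))
    flat <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(model = nm, fits[[nm]]$terms)))
    writeRegionTable(flat, out("model_results.tsv"))
    addFile(out("model_results.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    stages = stages,
    config_hash = configHash(config),
    files = lapply(setNames(nm = basename(files)), function(b)
      unname(tools::md5sum(file.path(config$outDir, b)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

configHash <- function(config) {
  config$outDir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a pipeline run against its recorded ground truth
#'
#' Tabulates the ALPS index against the phantom's analytic expectation and
#' each fitted standardized coefficient against the generating effect map,
#' flagging estimates whose 95% confidence interval misses the truth.
#'
#' @param outDir the pipeline output directory (containing manifest.json)
#' @return list with \code{alps} (data.frame or NULL), \code{effects}
#'   (data.frame or NULL) and \code{ok} (logical: all recoveries within
#'   tolerance)
#' @export
reportRun <- function(outDir) {
  manifestPath <- file.path(outDir, "manifest.json")
  if (!file.exists(manifestPath)) stop("no manifest.json in outDir")
  ok <- TRUE
  alps <- NULL
  pA <- file.path(outDir, "alps.json")
  pT <- file.path(outDir, "phantom_truth.json")
  if (file.exists(pA) && file.exists(pT)) {
    a <- jsonlite::read_json(pA)
    t <- jsonlite::read_json(pT)
    alps <- data.frame(quantity = "alps_index",
                       estimate = a$mean_index,
                       truth = t$expected_alps_index)
    alps$rel_error <- abs(alps$estimate - alps$truth) / alps$truth
    if (is.finite(t$snr) && alps$rel_error > 0.05) ok <- FALSE
    if (!is.finite(t$snr) && alps$rel_error > 1e-9) ok <- FALSE
  }
  effects <- NULL
  pM <- file.path(outDir, "model_results.json")
  pC <- file.path(outDir, "cohort_truth.json")
  if (file.exists(pM) && file.exists(pC)) {
    fits <- jsonlite::read_json(pM, simplifyVector = TRUE)
    truth <- jsonlite::read_json(pC, simplifyVector = TRUE)
    rows <- list()
    for (nm in names(fits)) {
      tm <- fits[[nm]]$terms
      outVar <- sub(" ~.*", "", fits[[nm]]$descriptor)
      tr <- truth$effects[[outVar]]
      for (i in seq_len(nrow(tm))) {
        tb <- tr[[tm$term[i]]]
        if (is.null(tb) || tm$term[i] == "sex") next
        covered <- abs(tm$beta[i] - tb) <= 1.96 * tm$se[i]
        rows[[length(rows) + 1L]] <-
          data.frame(model = nm, term = tm$term[i], truth = tb,
                     beta = tm$beta[i], se = tm$se[i], covered = covered)
      }
    }
    if (length(rows)) {
      effects <- do.call(rbind, rows)
      if (any(!effects$covered)) {
        ok <- FALSE
        for (i in which(!effects$covered))
          message(sprintf("FAIL: %s / %s (truth %.3f, estimate %.3f)",
                          effects$model[i], effects$term[i],
                          effects$truth[i], effects$beta[i]))
      }
    }
  }
  list(alps = alps, effects = effects, ok = ok)
}
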