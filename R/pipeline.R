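#' Read / write NIfTI volumes
#'
#' Thin adapters around RNifti keeping the affine attached to plain R
#' arrays (the internal volume representation). Data are written as
#' double precision so round trips preserve values.
#'
#' @param vol 3D/4D array with an "affine" attribute (or affine supplied).
#' @param path file path (.nii or .nii.gz).
#' @param affine optional 4x4 affine (1-based voxel convention).
#' @export
writeVolumeNifti <- function(vol, path, affine = NULL) {
  affine <- .volAffine(vol, affine)
  # RNifti uses 0-based voxel indices; shift the translation accordingly
  aff0 <- affine
  aff0[1:3, 4] <- aff0[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
  a <- vol
  attributes(a) <- list(dim = dim(vol))
  im <- RNifti::asNifti(a, datatype = "double")
  RNifti::sform(im) <- structure(aff0, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  im <- RNifti::readNifti(path)
  aff0 <- matrix(as.numeric(RNifti::xform(im)), 4, 4)
  aff <- aff0
  aff[1:3, 4] <- aff0[1:3, 4] - aff0[1:3, 1:3] %*% rep(1, 3)
  out <- array(as.numeric(im), dim(im))
  attr(out, "affine") <- aff
  out
}

#' Read / write tabular adapters
#'
#' Motion tables are TSV with six named columns; clinical score tables are
#' long TSV (subject, scale, timepoint, value). Malformed rows raise an
#' error naming the line.
#'
#' @param x table to write.
#' @param path file path.
#' @name tableAdapters
#' @export
writeMotionTsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname tableAdapters
#' @export
readMotionTsv <- function(path) {
  as.matrix(.readStrictTsv(path, nCol = 6, numericCols = 1:6))
}

#' @rdname tableAdapters
#' @export
writeScoresTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tableAdapters
#' @export
readScoresTsv <- function(path) {
  .readStrictTsv(path, nCol = 4, numericCols = 4)
}

# Strict TSV reader: every row must have the header's field count and the
# stated columns must parse as numbers; violations name the line.
.readStrictTsv <- function(path, nCol = NULL, numericCols = integer(0)) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (!is.null(nCol) && length(header) != nCol)
    stop(sprintf("%s: expected %d columns, header has %d", path, nCol,
                 length(header)))
  n <- length(header)
  rows <- parts[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n)
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 1,
                   length(rows[[i]]), n))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (j in numericCols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("%s: line %d, column '%s' is not numeric", path,
                   bad[1] + 1, header[j]))
    df[[j]] <- v
  }
  df
}

#' Published per-patient stimulation targets and outcomes
#'
#' The reference cohort table of the open-label accelerated iTBS study
#' this pipeline models: for each of the 26 analyzable patients, the MNI
#' coordinates of the individualized DLPFC stimulation target, its
#' superficial depth, the resting motor threshold, and the percent
#' reductions on BSI-CV, HAMD-17 and MADRS immediately after treatment.
#'
#' @return data.frame with 26 rows.
#' @export
referenceTargets <- function() {
  path <- system.file("extdata", "stimulation_targets_outcomes.tsv",
                      package = "specdcm", mustWork = TRUE)
  .readStrictTsv(path, nCol = 9, numericCols = 2:9)
}

#' Published cohort scale summary (means and SDs by timepoint)
#'
#' @return data.frame: scale, timepoint, mean, sd.
#' @export
referenceScaleSummary <- function() {
  path <- system.file("extdata", "cohort_scale_summary.tsv",
                      package = "specdcm", mustWork = TRUE)
  .readStrictTsv(path, nCol = 4, numericCols = 3:4)
}

#' JSON adapters for posteriors and configuration
#'
#' @param post \linkS4class{DcmPosterior}.
#' @param path file path.
#' @export
writePosteriorJson <- function(post, path) {
  jsonlite::write_json(list(mean = as.list(post@mean),
                            cov = post@cov,
                            freeEnergy = post@freeEnergy,
                            iterations = post@iterations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePosteriorJson
#' @export
readPosteriorJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DcmPosterior", mean = unlist(x$mean), cov = as.matrix(x$cov),
      freeEnergy = x$freeEnergy, iterations = x$iterations,
      trace = numeric(0))
}

#' Pipeline configuration
#'
#' Resolves all stage parameters into one serializable list; every run
#' writes the resolved configuration beside its outputs so results are
#' reproducible from the output directory alone.
#'
#' @param cohort a \code{cohortConfig()} (the synthetic study conditions).
#' @param nDiscard initial volumes discarded.
#' @param motionLimit exclusion limit (mm and degrees).
#' @param band bandpass edges (Hz).
#' @param fwhm smoothing kernel (mm).
#' @param alpha signed-map threshold (two-sided, uncorrected).
#' @param arOrder,nFreq cross-spectral settings.
#' @param models named list: model name -> region subset (default NCECM =
#'   target + negatively coupled regions; PCECM when its regions exist).
#' @param ppThreshold reporting threshold on BMA posterior probability.
#' @param stages character vector of enabled stages.
#' @param seed global seed; per-stage substreams are derived from it.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           nDiscard = 10, motionLimit = 3.5,
                           band = c(0.01, 0.1), fwhm = 6, alpha = 0.05,
                           arOrder = 8, nFreq = 32,
                           models = NULL, ppThreshold = 0.95,
                           stages = pipelineStages(),
                           seed = 1) {
  rn <- cohort$region_names
  if (is.null(models)) {
    neg <- intersect(c("DLPFC", "PCUN", "HIP", "INS", "sgACC"), rn)
    pos <- intersect(c("DLPFC", "CAU", "mPFC"), rn)
    models <- list()
    if (length(neg) >= 2) models$NCECM <- neg
    if (length(pos) >= 2) models$PCECM <- pos
  }
  list(cohort = cohort, nDiscard = nDiscard, motionLimit = motionLimit,
       band = band, fwhm = fwhm, alpha = alpha, arOrder = arOrder,
       nFreq = nFreq, models = models, ppThreshold = ppThreshold,
       stages = stages, seed = as.integer(seed))
}

#' @rdname pipelineConfig
#' @export
pipelineStages <- function() {
  c("simulate", "preprocess", "target", "fcmap", "dcm", "peb", "clinical")
}

# Stable per-stage substream seed from the global seed and stage name.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  (seed * 7919L + h) %% 2000000000L
}

#' Run the end-to-end analysis on a synthetic cohort
#'
#' Executes the enabled stages in fixed order — simulate, preprocess
#' (motion screening, detrend, confound regression; spectral features are
#' taken before bandpass), subject-wise spectral DCM inversion per model,
#' hierarchical PEB with model search and averaging, and the clinical
#' outcome layer — writing resolved configuration, per-stage outputs and
#' a run manifest to \code{outDir}.
#'
#' @param config from \code{pipelineConfig()}.
#' @param outDir output directory (created).
#' @return the run manifest (invisibly written as manifest.json).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), warnings = character(0),
                   version = as.character(utils::packageVersion("specdcm")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  cfgOut <- config
  cfgOut$cohort <- cfgOut$cohort[!vapply(cfgOut$cohort, isS4, TRUE)]
  jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  stageOn <- function(s) s %in% config$stages
  addStage <- function(name, outputs) {
    manifest$stages[[name]] <<- list(outputs = outputs)
  }

  cohortCfg <- config$cohort
  cohortCfg$seed <- .stageSeed(config$seed, "simulate")
  cohort <- generateCohort(cohortCfg)
  addStage("simulate", sprintf("%d subjects", length(cohort@subjects)))

  rois <- list()
  kept <- character(0)
  for (s in cohort@subjects) {
    if (stageOn("preprocess")) {
      dec <- lapply(s@sessions, function(ss)
        motionExclusion(ss$motion, config$motionLimit, config$motionLimit))
      if (!all(vapply(dec, `[[`, TRUE, "keep"))) next
      pp <- lapply(s@sessions, function(ss)
        preprocessSession(ss$roi, ss$motion, nDiscard = 0,
                          TR = cohortCfg$TR, band = config$band,
                          addGlobal = FALSE, bandpass = FALSE))
      rois[[s@subjectId]] <- lapply(pp, `[[`, "roi")
    } else {
      rois[[s@subjectId]] <- lapply(s@sessions, `[[`, "roi")
    }
    kept <- c(kept, s@subjectId)
  }
  addStage("preprocess",
           if (stageOn("preprocess"))
             sprintf("%d/%d sessions kept", length(kept),
                     length(cohort@subjects))
           else "skipped (raw series passed through)")

  # individualized target selection and FC profiles (volume cohorts only)
  labels <- cohort@config$labels
  dlpfcIdx <- match("DLPFC", cohortCfg$region_names)
  sgaccIdx <- match("sgACC", cohortCfg$region_names)
  if (stageOn("target") && !is.null(labels) && !is.na(dlpfcIdx) &&
      !is.na(sgaccIdx)) {
    targetTab <- NULL
    zMaps <- list()
    for (s in cohort@subjects) {
      if (!s@subjectId %in% kept) next
      vol <- s@sessions$pre$volume
      sel <- selectTarget(vol, labels == dlpfcIdx, labels,
                          sgaccLabels = sgaccIdx)
      targetTab <- rbind(targetTab,
                         data.frame(subject = s@subjectId,
                                    x = sel$coordinate[1],
                                    y = sel$coordinate[2],
                                    z = sel$coordinate[3], r = sel$r))
      if (stageOn("fcmap")) {
        seedTc <- seedTimecourse(vol, sel$coordinate, radius = 6)
        zMaps[[s@subjectId]] <- fisherZ(fcMap(seedTc, vol)$r)
      }
    }
    write.table(targetTab, file.path(outDir, "targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    addStage("target", "targets.tsv")
    if (stageOn("fcmap") && length(zMaps) >= 3) {
      gm <- groupSignedMaps(zMaps, alpha = config$alpha)
      addStage("fcmap", sprintf("signed maps: %d positive, %d negative voxels",
                                sum(gm$positive), sum(gm$negative)))
    }
  }

  # clinical classification feeds the PEB design
  clin <- clinicalScores(cohort)
  clin <- clin[clin$subject %in% kept, ]
  flagFor <- function(sub, scale) {
    b <- clin$value[clin$subject == sub & clin$scale == scale &
                      clin$timepoint == "baseline"]
    f <- clin$value[clin$subject == sub & clin$scale == scale &
                      clin$timepoint == "post"]
    isTRUE(classifyOutcome(scale, b, f)$response)
  }
  flags <- data.frame(
    subject = kept,
    responder_si = vapply(kept, flagFor, TRUE, scale = "BSI-CV"),
    responder_dep = vapply(kept, flagFor, TRUE, scale = "HAMD-17"))

  results <- list()
  if (stageOn("dcm")) {
    for (mdl in names(config$models)) {
      regions <- config$models[[mdl]]
      posts <- list()
      tab <- NULL
      for (sub in kept) for (sess in c("pre", "post")) {
        roi <- rois[[sub]][[sess]][, regions, drop = FALSE]
        posts[[paste(sub, sess, sep = ":")]] <-
          invertSubject(roi, TR = cohortCfg$TR, arOrder = config$arOrder,
                        nFreq = config$nFreq)
        tab <- rbind(tab, data.frame(subject = sub, session = sess))
      }
      results[[mdl]] <- list(posteriors = posts, table = tab)
    }
    addStage("dcm", sprintf("%d inversions x %d models",
                            2 * length(kept), length(config$models)))
  }

  if (stageOn("peb") && stageOn("dcm")) {
    for (mdl in names(results)) {
      tab <- merge(results[[mdl]]$table, flags, by = "subject", sort = FALSE)
      X <- buildDesign(tab)
      peb <- pebFit(results[[mdl]]$posteriors, X)
      avg <- bma(greedySearch(peb))
      edges <- do.call(rbind, lapply(seq_along(avg@mean), function(i) {
        nm <- names(avg@mean)[i]
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        pp <- strsplit(parts[2], "_", fixed = TRUE)[[1]]
        data.frame(covariate = parts[1],
                   destination = if (pp[1] %in% c("a", "self")) pp[2] else NA,
                   source = if (pp[1] == "a") pp[3] else
                     if (pp[1] == "self") pp[2] else NA,
                   mean = avg@mean[i], probability = avg@pp[i])
      }))
      write.table(edges, file.path(outDir, paste0("bma_", mdl, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results[[mdl]]$bma <- avg
      results[[mdl]]$peb <- peb
    }
    addStage("peb", paste0("bma_", names(results), ".tsv"))
  }

  if (stageOn("clinical")) {
    rates <- summarizeRates(
      "BSI-CV",
      clin$value[clin$scale == "BSI-CV" & clin$timepoint == "baseline"],
      clin$value[clin$scale == "BSI-CV" & clin$timepoint == "post"])
    jsonlite::write_json(rates, file.path(outDir, "clinical_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    addStage("clinical", "clinical_summary.json")
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results, cohort = cohort,
                 kept = kept))
}
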