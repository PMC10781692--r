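#' Accessors
#'
#' Small accessor generics for the package's S4 containers; user code should
#' use these rather than reaching into slots.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("connMatrix", function(object) standardGeneric("connMatrix"))
#' @rdname accessors
#' @export
setMethod("connMatrix", "EffectiveConnectivity", function(object) {
  m <- object@values
  dimnames(m) <- list(object@regionNames, object@regionNames)
  m
})

#' @rdname accessors
#' @export
setGeneric("regionNames", function(object) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setMethod("regionNames", "EffectiveConnectivity", function(object) object@regionNames)
#' @rdname accessors
#' @export
setMethod("regionNames", "CrossSpectra", function(object) object@regionNames)

#' @rdname accessors
#' @export
setGeneric("freqGrid", function(object) standardGeneric("freqGrid"))
#' @rdname accessors
#' @export
setMethod("freqGrid", "CrossSpectra", function(object) object@freq)

#' @rdname accessors
#' @export
setGeneric("csdArray", function(object) standardGeneric("csdArray"))
#' @rdname accessors
#' @export
setMethod("csdArray", "CrossSpectra", function(object) object@csd)

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "DcmPosterior", function(object) object@mean)
#' @rdname accessors
#' @export
setMethod("posteriorMean", "PebModel", function(object)
  setNames(object@theta2Mean, object@paramNames))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "BmaResult", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))
#' @rdname accessors
#' @export
setMethod("posteriorCov", "DcmPosterior", function(object) object@cov)
#' @rdname accessors
#' @export
setMethod("posteriorCov", "PebModel", function(object) object@theta2Cov)

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "DcmPosterior", function(object) object@freeEnergy)
#' @rdname accessors
#' @export
setMethod("freeEnergy", "PebModel", function(object) object@freeEnergy)

#' @rdname accessors
#' @export
setGeneric("posteriorProb", function(object) standardGeneric("posteriorProb"))
#' @rdname accessors
#' @export
setMethod("posteriorProb", "BmaResult", function(object) object@pp)

#' @rdname accessors
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setMethod("subjects", "Cohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("cohortConfigOf", function(object) standardGeneric("cohortConfigOf"))
#' @rdname accessors
#' @export
setMethod("cohortConfigOf", "Cohort", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("clinicalScores", function(object) standardGeneric("clinicalScores"))
#' @rdname accessors
#' @export
setMethod("clinicalScores", "SubjectRecord", function(object) object@clinical)
#' @rdname accessors
#' @export
setMethod("clinicalScores", "Cohort", function(object) {
  do.call(rbind, lapply(object@subjects, function(s) {
    cbind(subject = s@subjectId, s@clinical, stringsAsFactors = FALSE)
  }))
})

setMethod("show", "EffectiveConnectivity", function(object) {
  cat(sprintf("EffectiveConnectivity: %d regions\n", nrow(object@values)))
  print(round(connMatrix(object), 3))
})

setMethod("show", "CrossSpectra", function(object) {
  cat(sprintf("CrossSpectra (%s): %d regions, %d frequencies [%.4g, %.4g] Hz\n",
              object@source, dim(object@csd)[1], length(object@freq),
              min(object@freq), max(object@freq)))
})

setMethod("show", "DcmPosterior", function(object) {
  cat(sprintf("DcmPosterior: %d parameters, F = %.2f nats, %d iterations\n",
              length(object@mean), object@freeEnergy, object@iterations))
})

setMethod("show", "PebModel", function(object) {
  cat(sprintf("PebModel: %d rows x %d covariates, %d group parameters, F = %.2f\n",
              nrow(object@X), ncol(object@X), length(object@theta2Mean),
              object@freeEnergy))
})

setMethod("show", "BmaResult", function(object) {
  cat(sprintf("BmaResult: %d parameters averaged over %d models\n",
              length(object@mean), length(object@weights)))
  sig <- names(object@pp)[object@pp > 0.95]
  if (length(sig)) cat("  pp > 0.95:", paste(sig, collapse = ", "), "\n")
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: %d regions, %d/%d volumes (pre/post)\n",
              object@subjectId, ncol(object@sessions$pre$roi),
              nrow(object@sessions$pre$roi), nrow(object@sessions$post$roi)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects, %d regions, TR = %g s, seed = %d\n",
              length(object@subjects), object@config$n_regions,
              object@config$TR, object@config$seed))
})
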