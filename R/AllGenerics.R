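#' @include AllClasses.R
NULL

#' Accessors for pupilAAS classes
#'
#' Small read-only accessors for the package's S4 containers.  Slot access
#' via \code{@} is considered internal.
#'
#' @param object an object of the documented class.
#' @return The slot value (see the individual descriptions).
#' @name accessors
#' @aliases samplingRate pupilDiameter pupilTime isValid regressorValues
#'   regressorVariant nVolumes designMatrix designLabels kernelSamples
#'   peakTime hrfParams tStatistic arRho ttp nEvents eventOnsets boldMatrix
#'   trInterval cardiacPeakTimes
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("pupilDiameter", function(object) standardGeneric("pupilDiameter"))
#' @rdname accessors
#' @export
setGeneric("pupilTime", function(object) standardGeneric("pupilTime"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setGeneric("regressorValues",
           function(object) standardGeneric("regressorValues"))
#' @rdname accessors
#' @export
setGeneric("regressorVariant",
           function(object) standardGeneric("regressorVariant"))
#' @rdname accessors
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("designLabels", function(object) standardGeneric("designLabels"))
#' @rdname accessors
#' @export
setGeneric("kernelSamples", function(object) standardGeneric("kernelSamples"))
#' @rdname accessors
#' @export
setGeneric("peakTime", function(object) standardGeneric("peakTime"))
#' @rdname accessors
#' @export
setGeneric("hrfParams", function(object) standardGeneric("hrfParams"))
#' @rdname accessors
#' @export
setGeneric("tStatistic", function(object) standardGeneric("tStatistic"))
#' @rdname accessors
#' @export
setGeneric("arRho", function(object) standardGeneric("arRho"))
#' @rdname accessors
#' @export
setGeneric("ttp", function(object) standardGeneric("ttp"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("eventOnsets", function(object) standardGeneric("eventOnsets"))
#' @rdname accessors
#' @export
setGeneric("boldMatrix", function(object) standardGeneric("boldMatrix"))
#' @rdname accessors
#' @export
setGeneric("trInterval", function(object) standardGeneric("trInterval"))
#' @rdname accessors
#' @export
setGeneric("cardiacPeakTimes",
           function(object) standardGeneric("cardiacPeakTimes"))

setMethod("samplingRate", "PupilTrace", function(object) object@rate)
setMethod("pupilDiameter", "PupilTrace", function(object) object@diameter)
setMethod("pupilTime", "PupilTrace", function(object) object@time)
setMethod("isValid", "PupilTrace", function(object) object@valid)

setMethod("regressorValues", "PupilRegressor", function(object) object@values)
setMethod("regressorVariant", "PupilRegressor",
          function(object) object@variant)
setMethod("nVolumes", "PupilRegressor",
          function(object) length(object@values))

setMethod("nVolumes", "VolumeSeries", function(object) nrow(object@series))
setMethod("boldMatrix", "VolumeSeries", function(object) object@series)
setMethod("trInterval", "VolumeSeries", function(object) object@tr)

setMethod("designMatrix", "NuisanceDesign", function(object) object@design)
setMethod("designLabels", "NuisanceDesign",
          function(object) colnames(object@design))
setMethod("nVolumes", "NuisanceDesign", function(object) nrow(object@design))

setMethod("kernelSamples", "HRFKernel", function(object) object@samples)
setMethod("peakTime", "HRFKernel", function(object) object@peakTime)
setMethod("hrfParams", "HRFKernel", function(object) object@params)

setMethod("tStatistic", "GLMFit", function(object) object@tTarget)
setMethod("arRho", "GLMFit", function(object) object@ar1Rho)

setMethod("ttp", "HRFEstimate", function(object) object@ttp)
setMethod("nEvents", "HRFEstimate", function(object) object@nEvents)
setMethod("nEvents", "EventTrain", function(object) length(object@onsets))
setMethod("eventOnsets", "EventTrain", function(object) object@onsets)

setMethod("cardiacPeakTimes", "PhysioRecording",
          function(object) object@cardiacPeaks)

setMethod("show", "PupilTrace", function(object) {
  cat(sprintf("PupilTrace: %d samples at %g Hz (%.1f s), %.1f%% invalid\n",
              length(object@diameter), object@rate,
              length(object@diameter) / object@rate,
              100 * mean(!object@valid)))
  if (length(object@provenance))
    cat("  steps:", paste(unlist(object@provenance), collapse = " -> "),
        "\n")
})

setMethod("show", "PupilRegressor", function(object) {
  cat(sprintf(
    "PupilRegressor (%s): %d volumes at TR %g s, shift %g s\n",
    object@variant, length(object@values), object@tr, object@shiftApplied))
})

setMethod("show", "VolumeSeries", function(object) {
  cat(sprintf("VolumeSeries: %d volumes x %d ROI(s) at TR %g s\n",
              nrow(object@series), ncol(object@series), object@tr))
  cat("  ROIs:", paste(colnames(object@series), collapse = ", "), "\n")
})

setMethod("show", "NuisanceDesign", function(object) {
  cat(sprintf("NuisanceDesign: %d volumes x %d regressors\n",
              nrow(object@design), ncol(object@design)))
})

setMethod("show", "HRFKernel", function(object) {
  cat(sprintf(
    "HRFKernel: p1 = %g s, peak time %.2f s, %d samples at dt %g s\n",
    object@params@p1, object@peakTime, length(object@samples),
    object@params@dt))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: t(%s) = %.3f on %g dof, rho = %.3f\n",
              paste(object@targetLabel, collapse = "+"), object@tTarget,
              object@dof, object@ar1Rho))
})

setMethod("show", "HRFEstimate", function(object) {
  cat(sprintf(
    "HRFEstimate: TTP %.2f s from %d events (R2 = %.3f, shift %g s)\n",
    object@ttp, object@nEvents, object@fitR2, object@onsetShift))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %gs session, TR %gs, pupil %g Hz, mode '%s', seed %d\n",
    object@duration, object@tr, object@pupilRate, object@couplingMode,
    object@seed))
})
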