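#' @import methods
NULL

#' High-rate pupil trace with validity flags
#'
#' Container for an eye-tracker pupil recording on a uniform time grid.
#' The \code{valid} flags mark samples where the tracker reported a pupil
#' (blinks and signal losses are \code{FALSE}).  \code{rawInvalidFraction}
#' preserves the pre-interpolation invalid fraction for quality control,
#' and \code{provenance} records the preprocessing steps applied, in order.
#'
#' @slot time numeric, sample times in seconds (uniform grid, step 1/rate).
#' @slot diameter numeric, pupil diameter in arbitrary tracker units.
#' @slot valid logical, per-sample validity flag.
#' @slot rate numeric(1), sampling rate in Hz.
#' @slot rawInvalidFraction numeric(1), invalid fraction of the raw trace.
#' @slot provenance list of character step labels.
#' @exportClass PupilTrace
setClass("PupilTrace",
  representation(time = "numeric", diameter = "numeric", valid = "logical",
                 rate = "numeric", rawInvalidFraction = "numeric",
                 provenance = "list"),
  prototype(rawInvalidFraction = NA_real_, provenance = list()))

setValidity("PupilTrace", function(object) {
  msg <- character()
  n <- length(object@diameter)
  if (length(object@time) != n)
    msg <- c(msg, "time and diameter must have equal length")
  if (length(object@valid) != n)
    msg <- c(msg, "valid and diameter must have equal length")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (n >= 2L) {
    steps <- diff(object@time)
    if (any(steps <= 0) ||
        max(abs(steps - 1 / object@rate)) > 1e-6 / object@rate)
      msg <- c(msg, "time must increase with constant step 1/rate")
  }
  if (length(msg)) msg else TRUE
})

#' Volume-locked pupil regressor
#'
#' A pupil time series aligned to the fMRI volume grid, ready for GLM entry.
#'
#' @slot values numeric, one value per volume (demeaned before GLM entry).
#' @slot variant character(1), \code{"size"} or \code{"derivative"}.
#' @slot shiftApplied numeric(1), temporal shift applied upstream (seconds).
#' @slot tr numeric(1), repetition time in seconds.
#' @slot recomputedFraction numeric(1), fraction of high-rate samples dropped
#'   by the per-bin outlier rule during resampling.
#' @slot kernelTtp numeric(1), delay-of-response parameter of the HRF this
#'   regressor was convolved with, or \code{NA} if unconvolved.
#' @exportClass PupilRegressor
setClass("PupilRegressor",
  representation(values = "numeric", variant = "character",
                 shiftApplied = "numeric", tr = "numeric",
                 recomputedFraction = "numeric", kernelTtp = "numeric"),
  prototype(variant = "size", shiftApplied = 0, recomputedFraction = 0,
            kernelTtp = NA_real_))

setValidity("PupilRegressor", function(object) {
  msg <- character()
  if (!object@variant %in% c("size", "derivative"))
    msg <- c(msg, "variant must be 'size' or 'derivative'")
  if (!is.na(object@recomputedFraction) &&
      (object@recomputedFraction < 0 || object@recomputedFraction > 1))
    msg <- c(msg, "recomputedFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cardiac and respiratory recording
#'
#' Pulse (photoplethysmograph or equivalent) and respiratory belt traces
#' covering a scan, each on its own uniform grid starting at time 0.
#'
#' @slot pulse numeric, pulse trace.
#' @slot resp numeric, respiratory belt trace.
#' @slot pulseRate numeric(1), pulse sampling rate (Hz).
#' @slot respRate numeric(1), belt sampling rate (Hz).
#' @slot cardiacPeaks numeric, detected (or ground-truth) R-peak times in
#'   seconds; empty until detection.
#' @exportClass PhysioRecording
setClass("PhysioRecording",
  representation(pulse = "numeric", resp = "numeric", pulseRate = "numeric",
                 respRate = "numeric", cardiacPeaks = "numeric"),
  prototype(cardiacPeaks = numeric()))

setValidity("PhysioRecording", function(object) {
  msg <- character()
  if (object@pulseRate <= 0 || object@respRate <= 0)
    msg <- c(msg, "sampling rates must be positive")
  if (length(object@cardiacPeaks) >= 2L && any(diff(object@cardiacPeaks) <= 0))
    msg <- c(msg, "cardiacPeaks must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ROI-average BOLD series at TR resolution
#'
#' One column per region of interest, one row per volume.
#'
#' @slot series matrix, volumes x ROIs, with ROI column names.
#' @slot tr numeric(1), repetition time in seconds.
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(series = "matrix", tr = "numeric"))

setValidity("VolumeSeries", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (is.null(colnames(object@series)))
    msg <- c(msg, "series must carry ROI column names")
  if (length(msg)) msg else TRUE
})

#' Double-gamma HRF parameters
#'
#' The seven-parameter family behind the canonical hemodynamic response:
#' difference of two gamma densities.  \code{p1} is the delay of response
#' ("TTP" in sweep APIs), \code{p2} the delay of undershoot, \code{p3}/
#' \code{p4} the two dispersions, \code{p5} the response:undershoot ratio,
#' \code{p6} the onset and \code{p7} the kernel length, all in seconds
#' except the unitless \code{p5}.
#'
#' @slot p1,p2,p3,p4,p5,p6,p7 numeric(1) parameters (see description).
#' @slot dt numeric(1), kernel sampling step in seconds.
#' @exportClass HRFParams
setClass("HRFParams",
  representation(p1 = "numeric", p2 = "numeric", p3 = "numeric",
                 p4 = "numeric", p5 = "numeric", p6 = "numeric",
                 p7 = "numeric", dt = "numeric"),
  prototype(p1 = 6, p2 = 16, p3 = 1, p4 = 1, p5 = 6, p6 = 0, p7 = 32,
            dt = 0.1))

setValidity("HRFParams", function(object) {
  msg <- character()
  if (any(c(object@p1, object@p2, object@p3, object@p4) <= 0))
    msg <- c(msg, "p1, p2, p3 and p4 must be positive")
  if (object@p7 <= object@p1)
    msg <- c(msg, "kernel length p7 must exceed the response delay p1")
  if (object@dt <= 0)
    msg <- c(msg, "dt must be positive")
  k <- object@p7 / object@dt
  if (abs(k - round(k)) > 1e-8)
    msg <- c(msg, "dt must divide the kernel length p7")
  if (length(msg)) msg else TRUE
})

#' Sampled HRF kernel
#'
#' @slot samples numeric, kernel values on the grid \code{seq(0, p7, dt)}.
#' @slot params an \code{HRFParams} object.
#' @slot peakTime numeric(1), argmax of the sampled kernel in seconds.
#' @exportClass HRFKernel
setClass("HRFKernel",
  representation(samples = "numeric", params = "HRFParams",
                 peakTime = "numeric"))

#' Three-function HRF basis
#'
#' Canonical double-gamma kernel plus its temporal and dispersion
#' derivatives on a common time grid.
#'
#' @slot canonical,temporalDerivative,dispersionDerivative numeric vectors
#'   on the common grid.
#' @slot params the \code{HRFParams} of the canonical column.
#' @exportClass HRFBasisSet
setClass("HRFBasisSet",
  representation(canonical = "numeric", temporalDerivative = "numeric",
                 dispersionDerivative = "numeric", params = "HRFParams"))

setValidity("HRFBasisSet", function(object) {
  msg <- character()
  n <- length(object@canonical)
  if (length(object@temporalDerivative) != n ||
      length(object@dispersionDerivative) != n)
    msg <- c(msg, "basis columns must share a common grid")
  if (identical(object@canonical, object@temporalDerivative) ||
      identical(object@canonical, object@dispersionDerivative) ||
      identical(object@temporalDerivative, object@dispersionDerivative))
    msg <- c(msg, "basis columns must be mutually non-identical")
  if (length(msg)) msg else TRUE
})

#' Per-volume nuisance regressor matrix
#'
#' Movement and physiological noise design with labelled columns.
#'
#' @slot design matrix, volumes x columns, demeaned, with unique labels as
#'   column names.
#' @slot provenance list describing how each block was built.
#' @exportClass NuisanceDesign
setClass("NuisanceDesign",
  representation(design = "matrix", provenance = "list"),
  prototype(provenance = list()))

setValidity("NuisanceDesign", function(object) {
  msg <- character()
  labs <- colnames(object@design)
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "design columns must carry unique labels")
  if (ncol(object@design) &&
      any(apply(object@design, 2L, function(col) all(col == 0))))
    msg <- c(msg, "design must not contain constant-zero columns")
  if (length(msg)) msg else TRUE
})

#' First-level GLM fit
#'
#' Result of an AR(1)-prewhitened least-squares fit with a designated
#' target column (or contrast over target columns).
#'
#' @slot betas named numeric, coefficient estimates.
#' @slot residVar numeric(1), residual variance after prewhitening.
#' @slot dof numeric(1), residual degrees of freedom.
#' @slot tTarget numeric(1), t statistic of the target contrast.
#' @slot betaTarget numeric(1), estimate of the target contrast.
#' @slot seTarget numeric(1), standard error of the target contrast.
#' @slot ar1Rho numeric(1), estimated lag-1 residual autocorrelation.
#' @slot targetLabel character, label(s) of the target column(s).
#' @exportClass GLMFit
setClass("GLMFit",
  representation(betas = "numeric", residVar = "numeric", dof = "numeric",
                 tTarget = "numeric", betaTarget = "numeric",
                 seTarget = "numeric", ar1Rho = "numeric",
                 targetLabel = "character"))

setValidity("GLMFit", function(object) {
  msg <- character()
  if (abs(object@ar1Rho) >= 1)
    msg <- c(msg, "|ar1Rho| must be < 1")
  if (object@dof <= 0)
    msg <- c(msg, "residual degrees of freedom must be positive")
  if (length(msg)) msg else TRUE
})

#' Pseudo-event train
#'
#' Onsets (volume indices, 1-based) of suprathreshold excursions of a
#' standardized BOLD series, modelled as Dirac deltas for blind HRF
#' estimation.
#'
#' @slot onsets integer, strictly increasing volume indices.
#' @slot thresholdK numeric(1), threshold in SD units.
#' @exportClass EventTrain
setClass("EventTrain",
  representation(onsets = "integer", thresholdK = "numeric"))

setValidity("EventTrain", function(object) {
  if (length(object@onsets) >= 2L && any(diff(object@onsets) <= 0))
    "onsets must be strictly increasing" else TRUE
})

#' Blindly estimated HRF
#'
#' @slot kernel numeric, reconstructed kernel on a fine grid.
#' @slot dt numeric(1), fine-grid step in seconds.
#' @slot ttp numeric(1), argmax of the reconstructed kernel (seconds).
#' @slot nEvents integer(1), number of pseudo-events used.
#' @slot basisBetas numeric(3), canonical/temporal/dispersion coefficients.
#' @slot baseline numeric(1), fitted constant term.
#' @slot fitR2 numeric(1), proportion of variance explained.
#' @slot onsetShift numeric(1), onset-shift (seconds) selected by the fit.
#' @exportClass HRFEstimate
setClass("HRFEstimate",
  representation(kernel = "numeric", dt = "numeric", ttp = "numeric",
                 nEvents = "integer", basisBetas = "numeric",
                 baseline = "numeric", fitR2 = "numeric",
                 onsetShift = "numeric"))

setValidity("HRFEstimate", function(object) {
  msg <- character()
  if (object@ttp <= 0 || object@ttp > length(object@kernel) * object@dt)
    msg <- c(msg, "ttp must lie inside the kernel support")
  if (object@fitR2 < 0 || object@fitR2 > 1)
    msg <- c(msg, "fitR2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic-session configuration
#'
#' All knobs of the synthetic-data generator.  Defaults emulate the study
#' design the package targets: 5-minute sessions, TR = 2 s (150 volumes),
#' pupil sampled at 250 Hz with blink gaps, slow 0.04-0.1 Hz pupil
#' oscillations, ~1 Hz cardiac and ~0.3 Hz respiratory physiology.
#'
#' @slot duration numeric(1), session length in seconds.
#' @slot pupilRate numeric(1), pupil sampling rate in Hz.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nRois integer(1), number of simulated ROIs.
#' @slot couplingMode character(1), \code{"lag"}, \code{"hrf"} or
#'   \code{"none"}.
#' @slot couplingLag numeric(1), lag in seconds between pupil and BOLD in
#'   \code{"lag"} mode; negative values mean the pupil precedes the BOLD
#'   signal (the convention used by all coupling results).
#' @slot couplingTtp numeric(1), time-to-peak (delay-of-response parameter)
#'   of the transfer HRF in \code{"hrf"} mode.
#' @slot couplingGain numeric(1), amplitude of the coupled component.
#' @slot boldNoiseSd numeric(1), SD of white noise added to BOLD.
#' @slot physioBleed numeric(1), amplitude of aliased cardiac/respiratory
#'   components added to BOLD.
#' @slot pupilLag numeric(1), physiological delay (seconds) of the pupil
#'   behind the neural signal driving it; the analysis' backward shift
#'   compensates this lag.
#' @slot blinkRate numeric(1), blink events per minute.
#' @slot oscBand numeric(2), pupil oscillation band in Hz.
#' @slot heartRate numeric(1), beats per minute.
#' @slot respRate numeric(1), breaths per minute.
#' @slot seed integer(1), RNG seed; fully determines the output.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(duration = "numeric", pupilRate = "numeric", tr = "numeric",
                 nRois = "integer", couplingMode = "character",
                 couplingLag = "numeric", couplingTtp = "numeric",
                 couplingGain = "numeric", boldNoiseSd = "numeric",
                 physioBleed = "numeric", pupilLag = "numeric",
                 blinkRate = "numeric",
                 oscBand = "numeric", heartRate = "numeric",
                 respRate = "numeric", seed = "integer"),
  prototype(duration = 300, pupilRate = 250, tr = 2, nRois = 3L,
            couplingMode = "lag", couplingLag = 0, couplingTtp = 6,
            couplingGain = 1, boldNoiseSd = 0.5, physioBleed = 0,
            pupilLag = 1, blinkRate = 15, oscBand = c(0.04, 0.1),
            heartRate = 60,
            respRate = 18, seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  nvol <- object@duration / object@tr
  if (abs(nvol - round(nvol)) > 1e-8)
    msg <- c(msg, "duration/tr must be an integer number of volumes")
  spv <- object@pupilRate * object@tr
  if (abs(spv - round(spv)) > 1e-8)
    msg <- c(msg, "pupilRate*tr must be an integer number of samples")
  if (!object@couplingMode %in% c("lag", "hrf", "none"))
    msg <- c(msg, "couplingMode must be 'lag', 'hrf' or 'none'")
  nyq <- 1 / (2 * object@tr)
  if (length(object@oscBand) != 2L || object@oscBand[1] <= 0 ||
      object@oscBand[2] <= object@oscBand[1] || object@oscBand[2] >= nyq)
    msg <- c(msg, "oscBand must lie within (0, Nyquist of the TR grid)")
  if (object@couplingMode == "lag") {
    k <- object@couplingLag / object@tr
    if (abs(k - round(k)) > 1e-8)
      msg <- c(msg, "couplingLag must be a multiple of tr")
  }
  if (object@heartRate <= 0 || object@respRate <= 0)
    msg <- c(msg, "heartRate and respRate must be positive")
  lagSamp <- object@pupilLag * object@pupilRate
  if (object@pupilLag < 0 || abs(lagSamp - round(lagSamp)) > 1e-8)
    msg <- c(msg, "pupilLag must be a non-negative multiple of 1/pupilRate")
  if (length(msg)) msg else TRUE
})
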