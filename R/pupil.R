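#' @include AllClasses.R utils.R
NULL

#' Construct a pupil trace
#'
#' @param time sample times in seconds (uniform grid) or \code{NULL} to
#'   build the grid from \code{rate}.
#' @param diameter pupil diameter samples.
#' @param valid per-sample validity flags (default all valid).
#' @param rate sampling rate in Hz.
#' @return A validated \linkS4class{PupilTrace}.
#' @examples
#' pupilTrace(diameter = sin(seq(0, 10, by = 0.004)), rate = 250)
#' @export
pupilTrace <- function(time = NULL, diameter, valid = NULL, rate = 250) {
  n <- length(diameter)
  if (n == 0L) stop("empty pupil trace")
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  if (is.null(valid)) valid <- rep(TRUE, n)
  obj <- new("PupilTrace", time = as.numeric(time),
             diameter = as.numeric(diameter), valid = as.logical(valid),
             rate = rate, rawInvalidFraction = mean(!valid),
             provenance = list())
  validObject(obj)
  obj
}

#' Interpolate blink gaps in a pupil trace
#'
#' Every run of invalid samples is widened by \code{pre} seconds before its
#' onset and \code{post} seconds after its offset, and the widened window is
#' replaced by linear interpolation between the nearest flanking valid
#' samples.  Blinks touching the trace boundary are filled by holding the
#' nearest valid value.  The original invalid fraction is retained in the
#' \code{rawInvalidFraction} slot for quality control.
#'
#' @param trace a \linkS4class{PupilTrace}.
#' @param pre widening before blink onset, seconds (default 0.1).
#' @param post widening after blink offset, seconds (default 0.4).
#' @return The interpolated \linkS4class{PupilTrace} with all samples
#'   flagged valid.
#' @examples
#' tr <- pupilTrace(diameter = c(rep(5, 100), rep(0, 20), rep(6, 100)),
#'                  valid = c(rep(TRUE, 100), rep(FALSE, 20),
#'                            rep(TRUE, 100)), rate = 250)
#' out <- interpolateBlinks(tr)
#' all(isValid(out))
#' @export
interpolateBlinks <- function(trace, pre = 0.1, post = 0.4) {
  stopifnot(is(trace, "PupilTrace"))
  n <- length(trace@diameter)
  invalid <- !trace@valid
  rawFraction <- if (is.na(trace@rawInvalidFraction)) mean(invalid) else
    trace@rawInvalidFraction
  if (!any(invalid)) {
    trace@rawInvalidFraction <- rawFraction
    trace@provenance <- c(trace@provenance, "interpolate")
    return(trace)
  }
  if (all(invalid)) stop("unrecoverable trace: all samples invalid")
  preN <- round(pre * trace@rate)
  postN <- round(post * trace@rate)
  ## widen each invalid run by [-pre, +post]
  r <- rle(invalid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- logical(n)
  for (i in which(r$values)) {
    a <- max(1L, starts[i] - preN)
    b <- min(n, ends[i] + postN)
    mask[a:b] <- TRUE
  }
  good <- which(!mask)
  if (length(good) == 0L)
    stop("unrecoverable trace: widened blink windows cover every sample")
  bad <- which(mask)
  filled <- stats::approx(good, trace@diameter[good], xout = bad,
                          rule = 2)$y
  diameter <- trace@diameter
  diameter[bad] <- filled
  new("PupilTrace", time = trace@time, diameter = diameter,
      valid = rep(TRUE, n), rate = trace@rate,
      rawInvalidFraction = rawFraction,
      provenance = c(trace@provenance, "interpolate"))
}

#' Invalid-sample fraction and session inclusion flag
#'
#' The fraction is computed from the raw (pre-interpolation) validity
#' flags; a session is excluded when strictly more than 25\% of its raw
#' samples are invalid.
#'
#' @param trace a \linkS4class{PupilTrace} (raw or interpolated; the raw
#'   invalid fraction is carried through interpolation).
#' @param threshold exclusion threshold on the invalid fraction
#'   (default 0.25, strict inequality).
#' @return A list: \code{fraction} and logical \code{include}.
#' @examples
#' qcInvalidFraction(pupilTrace(diameter = rnorm(1000) + 5, rate = 250))
#' @export
qcInvalidFraction <- function(trace, threshold = 0.25) {
  stopifnot(is(trace, "PupilTrace"))
  if (length(trace@diameter) == 0L) stop("empty pupil trace")
  fraction <- if (!is.na(trace@rawInvalidFraction))
    trace@rawInvalidFraction else mean(!trace@valid)
  list(fraction = fraction, include = !(fraction > threshold))
}

#' First-order derivative of a pupil trace
#'
#' Forward difference scaled by the sampling rate (units per second);
#' positive values reflect dilation.  The final value is repeated so the
#' length is preserved.
#'
#' @param trace an interpolated \linkS4class{PupilTrace}.
#' @return A \linkS4class{PupilTrace} holding the derivative.
#' @examples
#' tr <- pupilTrace(diameter = seq(0, 1, length.out = 251), rate = 250)
#' head(pupilDiameter(computeDerivative(tr)))
#' @export
computeDerivative <- function(trace) {
  stopifnot(is(trace, "PupilTrace"))
  x <- trace@diameter
  d <- diff(x) * trace@rate
  d <- c(d, d[length(d)])
  new("PupilTrace", time = trace@time, diameter = d, valid = trace@valid,
      rate = trace@rate, rawInvalidFraction = trace@rawInvalidFraction,
      provenance = c(trace@provenance, "derivative"))
}

#' Shift a pupil trace back in time
#'
#' Compensates the pupil's lag behind the underlying neural activity: the
#' output value at time \code{t} equals the input at \code{t + shift}.
#' Trailing samples are filled by holding the last value.
#'
#' @param trace a \linkS4class{PupilTrace}.
#' @param shift non-negative shift in seconds, a multiple of the sampling
#'   step (default 1).
#' @return The shifted \linkS4class{PupilTrace}.
#' @examples
#' tr <- pupilTrace(diameter = c(rep(0, 500), 1, rep(0, 499)), rate = 250)
#' which.max(pupilDiameter(shiftTrace(tr, 1)))  # moved 250 samples earlier
#' @export
shiftTrace <- function(trace, shift = 1) {
  stopifnot(is(trace, "PupilTrace"), shift >= 0)
  n <- length(trace@diameter)
  k <- shift * trace@rate
  if (abs(k - round(k)) > 1e-8)
    stop("shift must be a multiple of the sampling step 1/rate")
  k <- as.integer(round(k))
  if (k >= n) stop("shift exceeds the trace duration")
  x <- trace@diameter
  shifted <- c(x[(k + 1L):n], rep(x[n], k))
  new("PupilTrace", time = trace@time, diameter = shifted,
      valid = trace@valid, rate = trace@rate,
      rawInvalidFraction = trace@rawInvalidFraction,
      provenance = c(trace@provenance, sprintf("shift:%gs", shift)))
}

#' Resample a pupil trace to the volume grid
#'
#' Bins the high-rate trace into consecutive TR-length bins.  Within each
#' bin, samples further than \code{outlierK} SD from the bin mean are
#' dropped and the mean is recomputed from the survivors (the bin's own SD
#' is used, not the global SD).  Output length always equals
#' \code{nVolumes}; any trailing partial bin is truncated.
#'
#' @param trace a \linkS4class{PupilTrace}.
#' @param tr repetition time in seconds.
#' @param nVolumes number of volumes.
#' @param outlierK outlier threshold in bin-SD units (default 3).
#' @param variant regressor variant label carried into the result.
#' @param shiftApplied shift (seconds) applied upstream, for provenance.
#' @return A \linkS4class{PupilRegressor}.
#' @examples
#' tr <- pupilTrace(diameter = rnorm(75000) + 5, rate = 250)
#' resampleToVolumes(tr, tr = 2, nVolumes = 150)
#' @export
resampleToVolumes <- function(trace, tr, nVolumes, outlierK = 3,
                              variant = "size", shiftApplied = 0) {
  stopifnot(is(trace, "PupilTrace"))
  spv <- round(trace@rate * tr)
  need <- spv * nVolumes
  if (length(trace@diameter) < need)
    stop(sprintf("trace too short: %d samples but %d needed for %d volumes",
                 length(trace@diameter), need, nVolumes))
  bins <- matrix(trace@diameter[seq_len(need)], nrow = spv)
  m <- colMeans(bins)
  s <- sqrt(colMeans(bins^2) - m^2)
  s[s < 0] <- 0  # numeric guard
  keep <- abs(sweep(bins, 2L, m)) <= outlierK * rep(s, each = spv)
  keep[, s == 0] <- TRUE
  nKeep <- colSums(keep)
  values <- colSums(bins * keep) / pmax(nKeep, 1L)
  emptyBins <- nKeep == 0L
  if (any(emptyBins)) {
    warning(sprintf("%d bin(s) lost all samples to the outlier rule; %s",
                    sum(emptyBins), "falling back to the original bin mean"))
    values[emptyBins] <- m[emptyBins]
  }
  recomputed <- sum(spv - nKeep) / need
  new("PupilRegressor", values = values, variant = variant,
      shiftApplied = shiftApplied, tr = tr,
      recomputedFraction = recomputed)
}

#' Full pupil preprocessing pipeline
#'
#' Fixed-order pipeline: blink interpolation, optional first-order
#' derivative, backward temporal shift, and TR-bin resampling with
#' per-bin outlier rejection.  The order matters and is recorded in the
#' trace provenance along the way.
#'
#' @param trace a raw \linkS4class{PupilTrace}.
#' @param variant \code{"size"} or \code{"derivative"}.
#' @param shift backward shift in seconds (default 1; set 0 for the
#'   no-shift compatibility analysis).
#' @param tr repetition time in seconds.
#' @param nVolumes number of fMRI volumes.
#' @param outlierK per-bin outlier threshold in SD units.
#' @return A \linkS4class{PupilRegressor}.
#' @examples
#' sim <- simulatePupil(simulationConfig(seed = 1))
#' reg <- preprocessPupil(sim$trace, "size", tr = 2, nVolumes = 150)
#' nVolumes(reg)
#' @export
preprocessPupil <- function(trace, variant = c("size", "derivative"),
                            shift = 1, tr = 2, nVolumes = 150,
                            outlierK = 3) {
  variant <- match.arg(variant)
  out <- interpolateBlinks(trace)
  if (variant == "derivative") out <- computeDerivative(out)
  if (shift > 0) out <- shiftTrace(out, shift)
  resampleToVolumes(out, tr = tr, nVolumes = nVolumes, outlierK = outlierK,
                    variant = variant, shiftApplied = shift)
}
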