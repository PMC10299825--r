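#' @include AllClasses.R utils.R
NULL

#' Detect cardiac peaks in a pulse trace
#'
#' Local maxima above an adaptive threshold (midpoint of the trace's 10th
#' and 90th percentiles) with a 0.25 s refractory period.  Inter-beat
#' intervals outside [0.33, 2] s are flagged with a warning.
#'
#' @param recording a \linkS4class{PhysioRecording} (or numeric pulse
#'   trace, in which case \code{rate} must be given).
#' @param rate pulse sampling rate in Hz when \code{recording} is numeric.
#' @return Numeric vector of peak times in seconds.
#' @examples
#' rec <- simulatePhysio(simulationConfig(seed = 2))
#' head(detectCardiacPeaks(rec))
#' @export
detectCardiacPeaks <- function(recording, rate = NULL) {
  if (is(recording, "PhysioRecording")) {
    pulse <- recording@pulse
    rate <- recording@pulseRate
  } else {
    pulse <- as.numeric(recording)
    if (is.null(rate)) stop("rate must be supplied for a numeric pulse")
  }
  if (rate < 10) stop("pulse rate must be at least 10 Hz")
  n <- length(pulse)
  if (stats::sd(pulse) == 0)
    stop("flat-line pulse: no cardiac peaks detectable")
  q <- stats::quantile(pulse, c(0.1, 0.9), names = FALSE)
  threshold <- mean(q)
  isMax <- c(FALSE, diff(sign(diff(pulse))) < 0, FALSE)
  cand <- which(isMax & pulse > threshold)
  if (length(cand) == 0L) stop("no suprathreshold pulse maxima found")
  refractory <- 0.25 * rate
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
    else if (pulse[i] > pulse[keep[length(keep)]])
      keep[length(keep)] <- i
  }
  if (length(keep) < 2L)
    stop("fewer than two cardiac peaks: phase undefined")
  peaks <- (keep - 1) / rate
  ibi <- diff(peaks)
  if (any(ibi < 0.33 | ibi > 2))
    warning(sprintf("%d inter-beat interval(s) outside [0.33, 2] s",
                    sum(ibi < 0.33 | ibi > 2)))
  peaks
}

#' Cardiac phase at given times
#'
#' Linear phase within each inter-beat interval:
#' \code{2 * pi * (t - prev) / (next - prev)}, in \code{[0, 2*pi)}.
#' Times outside the peak range are handled by extrapolating the nearest
#' interval.
#'
#' @param t numeric times in seconds.
#' @param peaks strictly increasing cardiac peak times.
#' @return Phase in radians, one value per element of \code{t}.
#' @examples
#' cardiacPhase(c(0, 0.25, 0.5), peaks = 0:10)
#' @export
cardiacPhase <- function(t, peaks) {
  if (length(peaks) < 2L) stop("need at least two peaks")
  if (any(diff(peaks) <= 0)) stop("peaks must be strictly increasing")
  idx <- findInterval(t, peaks)
  idx <- pmin(pmax(idx, 1L), length(peaks) - 1L)
  prev <- peaks[idx]
  nxt <- peaks[idx + 1L]
  phi <- 2 * pi * (t - prev) / (nxt - prev)
  phi %% (2 * pi)
}

#' Respiratory phase of a belt trace
#'
#' Histogram-equalized amplitude phase, signed by the respiratory
#' derivative: \code{phi(t) = pi * H(b(t)) * sign(db/dt)} where \code{H}
#' is the empirical CDF of the belt amplitude, giving values in
#' \code{(-pi, pi]} that separate inhalation from exhalation.  The
#' rank-based construction makes the phase invariant to affine rescaling
#' of the belt signal.
#'
#' @param resp numeric belt trace (or a \linkS4class{PhysioRecording}).
#' @param rate belt sampling rate in Hz (taken from the recording when one
#'   is given); used only for derivative smoothing.
#' @return Numeric phase series in radians, same length as the trace.
#' @examples
#' rec <- simulatePhysio(simulationConfig(seed = 2))
#' range(respiratoryPhase(rec))
#' @export
respiratoryPhase <- function(resp, rate = NULL) {
  if (is(resp, "PhysioRecording")) {
    rate <- resp@respRate
    resp <- resp@resp
  }
  resp <- as.numeric(resp)
  if (stats::sd(resp) == 0) stop("constant respiration trace")
  b <- (resp - mean(resp)) / stats::sd(resp)   # affine-invariant form
  H <- stats::ecdf(b)(b)
  d <- c(diff(b), 0)
  d[length(d)] <- d[length(d) - 1L]
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  pi * H * sgn
}

#' Fourier expansion of a physiological phase
#'
#' RETROICOR-style regressors \code{sin(m * phi)}, \code{cos(m * phi)} for
#' \code{m = 1..order}, one row per volume.
#'
#' @param phase numeric phase per volume (radians), evaluated at each
#'   volume's acquisition midpoint.
#' @param order Fourier order (default 5).
#' @param prefix column-label prefix (e.g. \code{"card"} or \code{"resp"}).
#' @return A volumes x \code{2 * order} matrix with labelled columns.
#' @examples
#' dim(phaseFourierRegressors(runif(150, 0, 2 * pi)))
#' @export
phaseFourierRegressors <- function(phase, order = 5, prefix = "card") {
  m <- seq_len(order)
  sins <- sapply(m, function(k) sin(k * phase))
  coss <- sapply(m, function(k) cos(k * phase))
  out <- cbind(sins, coss)
  colnames(out) <- c(paste0(prefix, "_sin", m), paste0(prefix, "_cos", m))
  out
}

## sliding-window helper: value per volume midpoint from a window of
## half-width w/2 seconds
.windowAt <- function(tVol, w, fun) {
  vapply(tVol, function(tc) fun(tc - w / 2, tc + w / 2), numeric(1))
}

#' Slow cardiorespiratory regressors
#'
#' Six per-volume regressors: heart-rate frequency (1 / mean inter-beat
#' interval in a 6 s window), heart-rate variability (SD of those
#' intervals), raw belt amplitude (mean in the TR bin), respiratory
#' frequency (zero-crossing count in a 12 s window), respiratory amplitude
#' (max - min belt excursion per window) and respiration volume per time
#' (excursion divided by breath period).  Windows without beats or breaths
#' carry the previous value forward with a warning.
#'
#' @param recording a \linkS4class{PhysioRecording} with detected (or
#'   ground-truth) \code{cardiacPeaks}; when empty, peaks are detected
#'   first.
#' @param nVolumes number of volumes.
#' @param tr repetition time in seconds.
#' @param cardiacWindow,respWindow window lengths in seconds (6 and 12).
#' @return A volumes x 6 matrix with labelled columns.
#' @examples
#' rec <- simulatePhysio(simulationConfig(seed = 2))
#' head(slowPhysioRegressors(rec, nVolumes = 150, tr = 2))
#' @export
slowPhysioRegressors <- function(recording, nVolumes, tr,
                                 cardiacWindow = 6, respWindow = 12) {
  stopifnot(is(recording, "PhysioRecording"))
  peaks <- recording@cardiacPeaks
  if (length(peaks) < 2L) peaks <- detectCardiacPeaks(recording)
  tVol <- (seq_len(nVolumes) - 1) * tr + tr / 2
  resp <- recording@resp
  fsR <- recording@respRate
  tResp <- (seq_along(resp) - 1) / fsR
  respC <- resp - mean(resp)

  hrFun <- function(a, b) {
    p <- peaks[peaks >= a & peaks <= b]
    if (length(p) < 2L) return(NA_real_)
    1 / mean(diff(p))
  }
  hrvFun <- function(a, b) {
    p <- peaks[peaks >= a & peaks <= b]
    if (length(p) < 3L) return(NA_real_)
    stats::sd(diff(p))
  }
  nR <- length(resp)
  respIdxRange <- function(a, b) {
    lo <- max(1L, floor(a * fsR) + 1L)
    hi <- min(nR, ceiling(b * fsR))
    if (lo > hi) integer(0) else lo:hi
  }
  beltFun <- function(a, b) {
    idx <- respIdxRange(a, b)
    if (length(idx) == 0L) return(NA_real_)
    mean(resp[idx])
  }
  respWinFun <- function(a, b) {
    idx <- respIdxRange(a, b)
    if (length(idx) < 3L) return(c(NA_real_, NA_real_, NA_real_))
    seg <- respC[idx]
    zc <- sum(diff(sign(seg)) != 0)
    freq <- zc / 2 / (length(seg) / fsR)           # breaths per second
    amp <- max(resp[idx]) - min(resp[idx])
    rvt <- if (freq > 0) amp * freq else NA_real_  # excursion / period
    c(freq, amp, rvt)
  }

  hrFreq <- .windowAt(tVol, cardiacWindow, hrFun)
  hrv <- .windowAt(tVol, cardiacWindow, hrvFun)
  beltRaw <- vapply(tVol, function(tc) beltFun(tc - tr / 2, tc + tr / 2),
                    numeric(1))
  respTriple <- t(vapply(tVol,
    function(tc) respWinFun(tc - respWindow / 2, tc + respWindow / 2),
    numeric(3)))
  out <- cbind(hr_freq = hrFreq, hrv = hrv, belt_raw = beltRaw,
               resp_freq = respTriple[, 1], resp_amp = respTriple[, 2],
               rvt = respTriple[, 3])
  if (anyNA(out)) {
    warning("window(s) with no beats/breaths: carrying previous value forward")
    for (j in seq_len(ncol(out))) {
      col <- out[, j]
      if (is.na(col[1])) col[1] <- col[which(!is.na(col))[1]]
      for (i in seq_along(col)[-1]) if (is.na(col[i])) col[i] <- col[i - 1]
      out[, j] <- col
    }
  }
  out
}

#' Assemble the 33-column movement and physiological nuisance design
#'
#' Concatenates the six motion parameters, ten cardiac-phase and ten
#' respiratory-phase Fourier regressors, six slow cardiorespiratory
#' regressors and one ventricle noise regressor; each column is demeaned
#' and labelled.  The full design has 33 columns (26 of them the
#' RETROICOR block: 10 + 10 + 6).
#'
#' @param motion volumes x 6 motion-parameter matrix (or \code{NULL} to
#'   omit the block; same for the other blocks).
#' @param cardiac volumes x 10 cardiac-phase Fourier block.
#' @param resp volumes x 10 respiratory-phase Fourier block.
#' @param slow volumes x 6 slow cardiorespiratory block.
#' @param ventricle numeric ventricle series (one column).
#' @return A \linkS4class{NuisanceDesign}.
#' @examples
#' nd <- assembleNuisanceDesign(motion = matrix(rnorm(150 * 6), 150),
#'                              ventricle = rnorm(150))
#' designLabels(nd)
#' @export
assembleNuisanceDesign <- function(motion = NULL, cardiac = NULL,
                                   resp = NULL, slow = NULL,
                                   ventricle = NULL) {
  blocks <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(ncol(motion) == 6L)
    colnames(motion) <- paste0("motion_", 1:6)
    blocks$motion <- motion
  }
  if (!is.null(cardiac)) blocks$cardiac <- as.matrix(cardiac)
  if (!is.null(resp)) blocks$resp <- as.matrix(resp)
  if (!is.null(slow)) blocks$slow <- as.matrix(slow)
  if (!is.null(ventricle))
    blocks$ventricle <- matrix(as.numeric(ventricle),
                               dimnames = list(NULL, "ventricle"))
  if (length(blocks) == 0L) stop("no nuisance blocks supplied")
  nvols <- vapply(blocks, nrow, integer(1))
  if (length(unique(nvols)) != 1L)
    stop("all nuisance blocks must share the volume count")
  design <- do.call(cbind, unname(blocks))
  design <- sweep(design, 2L, colMeans(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[-qrd$pivot[seq_len(qrd$rank)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  new("NuisanceDesign", design = design,
      provenance = list(blocks = names(blocks)))
}

#' Build the full nuisance design for one session
#'
#' Convenience wrapper: detects cardiac peaks, evaluates cardiac and
#' respiratory phases at each volume's acquisition midpoint, expands both
#' to 5th-order Fourier sets, computes the six slow regressors, and
#' assembles everything with the motion and ventricle blocks into the
#' 33-column design.
#'
#' @param physio a \linkS4class{PhysioRecording}.
#' @param motion volumes x 6 motion matrix.
#' @param ventricle numeric ventricle series.
#' @param nVolumes number of volumes.
#' @param tr repetition time in seconds.
#' @param order Fourier order (default 5).
#' @return A \linkS4class{NuisanceDesign} with 33 columns.
#' @examples
#' sess <- simulateSession(simulationConfig(seed = 3))
#' nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
#'                           nVolumes = 150, tr = 2)
#' ncol(designMatrix(nd))
#' @export
buildNuisanceDesign <- function(physio, motion, ventricle, nVolumes, tr,
                                order = 5) {
  peaks <- detectCardiacPeaks(physio)
  tMid <- (seq_len(nVolumes) - 1) * tr + tr / 2
  cardPhi <- cardiacPhase(tMid, peaks)
  respPhiFull <- respiratoryPhase(physio)
  respIdx <- pmin(pmax(round(tMid * physio@respRate) + 1L, 1L),
                  length(respPhiFull))
  respPhi <- respPhiFull[respIdx]
  cardiac <- phaseFourierRegressors(cardPhi, order, prefix = "card")
  resp <- phaseFourierRegressors(respPhi, order, prefix = "resp")
  physioPk <- physio
  physioPk@cardiacPeaks <- peaks
  slow <- slowPhysioRegressors(physioPk, nVolumes, tr)
  assembleNuisanceDesign(motion = motion, cardiac = cardiac, resp = resp,
                         slow = slow, ventricle = ventricle)
}
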