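#' @include AllClasses.R utils.R glm.R hrf.R
NULL

#' Systematic time-to-peak sweep
#'
#' Convolves the session pupil regressors with double-gamma kernels whose
#' delay-of-response parameter runs over \code{ttpGrid} (default 1-6 s),
#' and fits one first-level GLM per (TTP, variant) cell: a single
#' convolved pupil column per session plus the full nuisance model.  With
#' both variants supplied this is the 12-regressor sweep (6 kernels x
#' pupil size and derivative).
#'
#' @param boldSessions list over sessions of \linkS4class{VolumeSeries}
#'   (all ROIs) or numeric single-ROI series.
#' @param pupilSize list over sessions of \linkS4class{PupilRegressor}
#'   (variant \code{"size"}).
#' @param pupilDeriv optional list over sessions of derivative
#'   regressors; \code{NULL} restricts the sweep to pupil size.
#' @param nuisanceSessions list of \linkS4class{NuisanceDesign} or
#'   \code{NULL}.
#' @param tr repetition time in seconds.
#' @param ttpGrid delay parameters to sweep (default \code{1:6}).
#' @param cutoff high-pass cut-off period in seconds.
#' @return A data.frame with columns \code{roi}, \code{variant},
#'   \code{ttp}, \code{t}, \code{dof}, \code{rho}.  Cells whose GLM fails
#'   carry \code{NA} with the error in the \code{note} column.
#' @examples
#' sess <- simulateSession(simulationConfig(seed = 8, couplingMode = "lag"))
#' reg <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
#' sweep <- ttpSweep(list(sess$bold), list(reg), tr = 2)
#' head(sweep)
#' @export
ttpSweep <- function(boldSessions, pupilSize, pupilDeriv = NULL,
                     nuisanceSessions = NULL, tr, ttpGrid = 1:6,
                     cutoff = 128) {
  roiSeries <- function(b, roi) {
    if (is(b, "VolumeSeries")) b@series[, roi] else as.numeric(b)
  }
  rois <- if (is(boldSessions[[1]], "VolumeSeries"))
    colnames(boldSessions[[1]]@series) else "roi1"
  variants <- list(size = pupilSize)
  if (!is.null(pupilDeriv)) variants$derivative <- pupilDeriv
  out <- NULL
  kernels <- lapply(ttpGrid,
                    function(p1) doubleGammaHrf(hrfParameters(p1 = p1,
                                                              dt = tr)))
  for (roi in rois) {
    bold <- lapply(boldSessions, roiSeries, roi = roi)
    for (v in names(variants)) {
      for (i in seq_along(ttpGrid)) {
        conv <- lapply(variants[[v]], convolveAtTr, kernel = kernels[[i]])
        row <- tryCatch({
          fit <- pupilCouplingTstat(bold, conv, nuisanceSessions, tr,
                                    cutoff)
          data.frame(roi = roi, variant = v, ttp = ttpGrid[i],
                     t = fit@tTarget, dof = fit@dof, rho = fit@ar1Rho,
                     note = "")
        }, error = function(e) {
          data.frame(roi = roi, variant = v, ttp = ttpGrid[i],
                     t = NA_real_, dof = NA_real_, rho = NA_real_,
                     note = conditionMessage(e))
        })
        out <- rbind(out, row)
      }
    }
  }
  out
}

#' Lagged cross-correlation of pupil and BOLD
#'
#' \code{r(lag) = cor(bold(t), pupil(t + lag))} over the shrinking overlap
#' (no padding), for lags from \code{-maxLag} to \code{+maxLag} seconds in
#' steps of \code{step}.  Negative lags mean the pupil signal precedes the
#' BOLD signal; the convention is recorded in the result's
#' \code{"convention"} attribute so sign flips cannot pass silently.
#' Fisher z values (\code{atanh(r)}) are included.
#'
#' @param pupil \linkS4class{PupilRegressor} or numeric series at TR.
#' @param bold numeric (cleaned, demeaned) ROI series of equal length.
#' @param tr repetition time in seconds.
#' @param maxLag largest absolute lag in seconds (default 8).
#' @param step lag step in seconds (default 2); both must be TR multiples.
#' @return A data.frame with columns \code{lag_s}, \code{r}, \code{z}.
#' @examples
#' x <- rnorm(150)
#' crossCorrelateLags(x, x, tr = 2)
#' @export
crossCorrelateLags <- function(pupil, bold, tr, maxLag = 8, step = 2) {
  p <- if (is(pupil, "PupilRegressor")) pupil@values else
    as.numeric(pupil)
  b <- as.numeric(bold)
  if (length(p) != length(b))
    stop("pupil and BOLD series must have equal length")
  n <- length(b)
  lagsSec <- seq(-maxLag, maxLag, by = step)
  lagVol <- lagsSec / tr
  if (any(abs(lagVol - round(lagVol)) > 1e-8))
    stop("lags must be multiples of the TR")
  lagVol <- as.integer(round(lagVol))
  p <- .demean(p); b <- .demean(b)
  res <- vapply(lagVol, function(l) {
    i <- seq_len(n)
    ok <- i + l >= 1L & i + l <= n
    if (sum(ok) < 10L)
      stop("overlap shorter than 10 points at lag ", l * tr, " s")
    stats::cor(b[i[ok]], p[i[ok] + l])
  }, numeric(1))
  out <- data.frame(lag_s = lagsSec, r = res, z = fisherZ(res))
  attr(out, "convention") <- "negative lag: pupil precedes BOLD"
  out
}

#' Full and partial pupil-BOLD correlation at lag zero
#'
#' Residualizes both the pupil series and the target BOLD series on the
#' confound series (with intercept) and correlates the residuals;
#' the unresidualized correlation is returned alongside.
#'
#' @param pupil numeric (or \linkS4class{PupilRegressor}) series.
#' @param boldTarget numeric target ROI series.
#' @param boldConfound numeric confound ROI series (e.g. the LC signal
#'   when asking whether other nuclei couple to the pupil independently
#'   of the LC).
#' @return A list: \code{rFull}, \code{rPartial}, \code{zFull},
#'   \code{zPartial}.
#' @examples
#' p <- rnorm(150); conf <- rnorm(150)
#' partialCorrelationLag0(p, 0.5 * p + rnorm(150), conf)
#' @export
partialCorrelationLag0 <- function(pupil, boldTarget, boldConfound) {
  p <- if (is(pupil, "PupilRegressor")) pupil@values else
    as.numeric(pupil)
  y <- as.numeric(boldTarget)
  g <- as.numeric(boldConfound)
  if (stats::sd(g) == 0) stop("constant confound series")
  rFull <- stats::cor(y, p)
  X <- cbind(1, g)
  resP <- stats::residuals(stats::lm.fit(X, p))
  resY <- stats::residuals(stats::lm.fit(X, y))
  ## a series that is (numerically) an affine function of the confound
  ## leaves only floating-point dust: its partial correlation is zero
  rPartial <- if (stats::sd(resY) < 1e-10 * stats::sd(y) ||
                  stats::sd(resP) < 1e-10 * stats::sd(p)) 0 else
    stats::cor(resY, resP)
  list(rFull = rFull, rPartial = rPartial, zFull = fisherZ(rFull),
       zPartial = fisherZ(rPartial))
}

#' Welch cross-spectral density of pupil and BOLD
#'
#' Averaged cross-spectrum over tapered, overlapping segments (default:
#' 10-sample windows with 3 samples of overlap, Hann taper), zero-padded
#' to \code{nfft} points so that spectral peaks can be located on a grid
#' finer than a 10-sample window's native resolution.  Magnitude is
#' reported up to the Nyquist frequency \code{1/(2 tr)}.
#'
#' @param x,y numeric series of equal length (pupil and cleaned BOLD).
#' @param tr sampling interval in seconds (\code{fs = 1/tr}).
#' @param window segment length in samples (default 10).
#' @param overlap segment overlap in samples (default 3).
#' @param nfft transform length after zero padding (default 256).
#' @param taper \code{"hann"} (default) or \code{"rect"}.
#' @return A data.frame with columns \code{frequency_hz} and
#'   \code{cross_power}; attributes \code{peakFrequency} (argmax over
#'   f > 0) and \code{complexSpectrum} (full-length averaged complex
#'   cross-spectrum).
#' @examples
#' t0 <- seq(0, 298, by = 2)
#' x <- sin(2 * pi * 0.1 * t0)
#' csd <- crossSpectralDensity(x, x, tr = 2)
#' attr(csd, "peakFrequency")
#' @export
crossSpectralDensity <- function(x, y, tr, window = 10, overlap = 3,
                                 nfft = 256, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (window > n) stop("window exceeds the series length")
  if (overlap >= window) stop("overlap must be smaller than the window")
  if (nfft < window) stop("nfft must be at least the window length")
  fs <- 1 / tr
  w <- if (taper == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(window - 1)) / (window - 1)))
  } else rep(1, window)
  starts <- seq(1L, n - window + 1L, by = window - overlap)
  S <- complex(real = numeric(nfft), imaginary = numeric(nfft))
  for (s0 in starts) {
    idx <- s0:(s0 + window - 1L)
    xs <- .demean(x[idx]) * w
    ys <- .demean(y[idx]) * w
    X <- stats::fft(c(xs, numeric(nfft - window)))
    Y <- stats::fft(c(ys, numeric(nfft - window)))
    S <- S + Conj(X) * Y
  }
  S <- S / (length(starts) * sum(w^2) * fs)
  half <- seq_len(floor(nfft / 2) + 1L)
  freqs <- (half - 1L) * fs / nfft
  mag <- Mod(S[half])
  pos <- freqs > 0
  out <- data.frame(frequency_hz = freqs, cross_power = mag)
  attr(out, "peakFrequency") <- freqs[pos][which.max(mag[pos])]
  attr(out, "complexSpectrum") <- S
  attr(out, "nfft") <- nfft
  out
}
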