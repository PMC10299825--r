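#' @include AllClasses.R utils.R
NULL

#' Construct double-gamma HRF parameters
#'
#' The seven-parameter canonical family: \code{p1} delay of response
#' ("TTP"; the sweep varies it over 1-6 s), \code{p2} delay of undershoot
#' (16), \code{p3}/\code{p4} dispersions (1, 1), \code{p5}
#' response:undershoot ratio (6), \code{p6} onset (0), \code{p7} kernel
#' length (32 s).  Note that "TTP" names the delay parameter \code{p1},
#' not the kernel's argmax: the analytic mode of the positive lobe is
#' \code{(p1/p3 - 1) * p3 = p1 - p3}; the true argmax is exposed as
#' \code{peakTime} on the sampled kernel.
#'
#' @param p1,p2,p3,p4,p5,p6,p7 family parameters (see description).
#' @param dt sampling step in seconds.
#' @return A validated \linkS4class{HRFParams}.
#' @examples
#' hrfParameters(p1 = 2, dt = 2)
#' @export
hrfParameters <- function(p1 = 6, p2 = 16, p3 = 1, p4 = 1, p5 = 6,
                          p6 = 0, p7 = 32, dt = 0.1) {
  obj <- new("HRFParams", p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
             p6 = p6, p7 = p7, dt = dt)
  validObject(obj)
  obj
}

## raw (unnormalized) kernel values on seq(0, p7, dt)
.doubleGammaRaw <- function(params, p3 = params@p3, onset = params@p6) {
  t <- seq(0, params@p7, by = params@dt) - onset
  h <- stats::dgamma(t, shape = params@p1 / p3, scale = p3) -
    stats::dgamma(t, shape = params@p2 / params@p4, scale = params@p4) /
      params@p5
  h[t < 0] <- 0
  h
}

#' Double-gamma hemodynamic response kernel
#'
#' \code{h(t) = gammapdf(t; p1/p3, p3) - gammapdf(t; p2/p4, p4) / p5},
#' sampled on \code{[0, p7]} at step \code{dt}.  By default the kernel is
#' scaled to unit peak (GLM t statistics are invariant to positive
#' rescaling, so the normalization is cosmetic); \code{normalize = "sum"}
#' scales to unit positive-lobe mass instead, and \code{"none"} leaves the
#' gamma-density difference untouched.
#'
#' @param params an \linkS4class{HRFParams}.
#' @param normalize \code{"peak"} (default), \code{"sum"} or \code{"none"}.
#' @return An \linkS4class{HRFKernel} with its \code{peakTime} recorded.
#' @examples
#' k <- doubleGammaHrf(hrfParameters(p1 = 6, dt = 0.01))
#' peakTime(k)  # ~5 s: gamma mode (p1 - p3), nudged by the undershoot
#' @export
doubleGammaHrf <- function(params = hrfParameters(),
                           normalize = c("peak", "sum", "none")) {
  normalize <- match.arg(normalize)
  validObject(params)
  h <- .doubleGammaRaw(params)
  if (all(h == 0)) stop("degenerate kernel: all samples zero")
  h <- switch(normalize,
              peak = h / max(h),
              sum = h / sum(h[h > 0]),
              none = h)
  new("HRFKernel", samples = h, params = params,
      peakTime = (which.max(h) - 1L) * params@dt)
}

#' Canonical HRF basis with temporal and dispersion derivatives
#'
#' Three columns on the common grid of the canonical kernel: the canonical
#' double-gamma kernel, its temporal derivative (finite difference of the
#' onset, \code{[h(t - tdShift) - h(t)] / tdShift}, which approaches
#' \code{-dh/dt} as the shift vanishes), and its dispersion derivative
#' (finite difference with respect to \code{p3}, step 0.01).  Derivatives
#' are computed on the unnormalized kernels; the columns span the same
#' space under any positive rescaling.
#'
#' @param params an \linkS4class{HRFParams}.
#' @param tdShift onset step (seconds) for the temporal derivative.
#' @return An \linkS4class{HRFBasisSet}.
#' @examples
#' b <- hrfBasisSet(hrfParameters(dt = 0.1))
#' @export
hrfBasisSet <- function(params = hrfParameters(), tdShift = 1) {
  validObject(params)
  h <- .doubleGammaRaw(params)
  hLate <- .doubleGammaRaw(params, onset = params@p6 + tdShift)
  td <- (hLate - h) / tdShift
  dStep <- 0.01
  hDisp <- .doubleGammaRaw(params, p3 = params@p3 + dStep)
  dd <- (h - hDisp) / dStep
  obj <- new("HRFBasisSet", canonical = h, temporalDerivative = td,
             dispersionDerivative = dd, params = params)
  validObject(obj)
  obj
}

#' Convolve a volume-locked pupil regressor with an HRF kernel
#'
#' Causal discrete convolution on the TR grid, truncated to the regressor
#' length and demeaned.  The kernel must be sampled at the regressor's TR.
#'
#' @param regressor a \linkS4class{PupilRegressor}.
#' @param kernel an \linkS4class{HRFKernel} with \code{dt} equal to the
#'   regressor's TR.
#' @return A demeaned, convolved \linkS4class{PupilRegressor}; the
#'   kernel's delay parameter is recorded in the \code{kernelTtp} slot.
#' @examples
#' reg <- new("PupilRegressor", values = c(1, rep(0, 19)), tr = 2)
#' k <- doubleGammaHrf(hrfParameters(p1 = 2, dt = 2))
#' regressorValues(convolveAtTr(reg, k))
#' @export
convolveAtTr <- function(regressor, kernel) {
  stopifnot(is(regressor, "PupilRegressor"), is(kernel, "HRFKernel"))
  if (abs(kernel@params@dt - regressor@tr) > 1e-8)
    stop(sprintf("kernel dt (%g s) must equal the regressor TR (%g s)",
                 kernel@params@dt, regressor@tr))
  conv <- .causalConv(regressor@values, kernel@samples)
  new("PupilRegressor", values = .demean(conv),
      variant = regressor@variant, shiftApplied = regressor@shiftApplied,
      tr = regressor@tr, recomputedFraction = regressor@recomputedFraction,
      kernelTtp = kernel@params@p1)
}
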