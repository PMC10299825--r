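#' @include AllClasses.R utils.R glm.R hrf.R
NULL

#' Clean a BOLD series
#'
#' Regresses out the nuisance design and DCT drift (plus an intercept)
#' and z-scores the residual.  With \code{ar1 = TRUE} (the default, used
#' by the blind HRF estimation) the residual is additionally prewhitened
#' by the \code{(1, -rho)} filter before standardization.  The lagged
#' cross-correlation and cross-spectral analyses use \code{ar1 = FALSE}:
#' prewhitening is a differencing operation that would distort the
#' cross-correlation function of the smooth coupled component.
#'
#' @param bold numeric ROI series.
#' @param nuisance \linkS4class{NuisanceDesign}, matrix or \code{NULL}.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cut-off period in seconds.
#' @param ar1 prewhiten the residual (default \code{TRUE}).
#' @return A numeric standardized residual series (mean 0, SD 1).
#' @examples
#' cleanSignal(rnorm(150, 100, 2), NULL, tr = 2)[1:5]
#' @export
cleanSignal <- function(bold, nuisance = NULL, tr, cutoff = 128,
                        ar1 = TRUE) {
  y <- as.numeric(bold)
  nuis <- if (is(nuisance, "NuisanceDesign")) nuisance@design else
    if (!is.null(nuisance)) as.matrix(nuisance) else NULL
  X <- cbind(intercept = rep(1, length(y)),
             dctHighpassBasis(length(y), tr, cutoff), nuis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient cleaning design")
  e <- stats::residuals(stats::lm.fit(X, y))
  if (!ar1) return(.zscore(e))
  rho <- .ar1Rho(e)
  ## regression-induced bias correction (see fitAr1Glm)
  Q <- qr.Q(qrX)
  rho <- rho + sum(Q[-1, , drop = FALSE] *
                     Q[-nrow(Q), , drop = FALSE]) /
    (length(y) - qrX$rank)
  if (abs(rho) >= 0.99) {
    warning(sprintf("AR(1) estimate %.3f clamped to +/-0.99", rho))
    rho <- sign(rho) * 0.99
  }
  .zscore(drop(.prewhiten(matrix(e), rho)))
}

#' Detect spontaneous pseudo-events
#'
#' Onsets are the volumes where the standardized series crosses above
#' \code{+k} SD from below; a run of consecutive suprathreshold samples
#' yields a single event.  With \code{twoSided = TRUE}, downward crossings
#' below \code{-k} are detected as well (merged, sorted).
#'
#' @param clean numeric z-scored series.
#' @param k threshold in SD units (default 1).
#' @param twoSided also detect negative excursions (default \code{FALSE}).
#' @return An \linkS4class{EventTrain}; errors when no event is found.
#' @examples
#' eventOnsets(detectPseudoEvents(c(0, 0, 2, 2, 0, 0, 1.5, 0)))
#' @export
detectPseudoEvents <- function(clean, k = 1, twoSided = FALSE) {
  x <- as.numeric(clean)
  crossings <- function(v) {
    above <- v >= k
    which(above & !c(FALSE, above[-length(v)]))
  }
  onsets <- crossings(x)
  if (twoSided) onsets <- sort(unique(c(onsets, crossings(-x))))
  if (length(onsets) == 0L)
    stop("no suprathreshold events detected: HRF estimation impossible")
  new("EventTrain", onsets = as.integer(onsets), thresholdK = k)
}

## basis columns sampled on the TR grid (kernel grid is 0..p7 at dt)
.basisAtTr <- function(basis, tr) {
  dt <- basis@params@dt
  step <- tr / dt
  if (abs(step - round(step)) > 1e-8)
    stop("basis dt must divide the TR")
  idx <- seq(1L, length(basis@canonical), by = as.integer(round(step)))
  cbind(canonical = basis@canonical[idx],
        temporal = basis@temporalDerivative[idx],
        dispersion = basis@dispersionDerivative[idx])
}

#' Fit an HRF to a pseudo-event train
#'
#' For each candidate onset shift, the delta train (moved \code{s} volumes
#' earlier, toward the neural events that precede their BOLD expression)
#' is convolved with the three basis functions on the TR grid; the design
#' with these three columns plus an intercept is fitted by least squares
#' and the shift maximizing R-squared wins.  The kernel is reconstructed
#' from the basis coefficients on the basis' fine grid; its argmax is
#' reported as the time-to-peak.
#'
#' @param clean numeric z-scored series.
#' @param events an \linkS4class{EventTrain} (or integer onset vector).
#' @param basis an \linkS4class{HRFBasisSet} (fine grid, e.g. dt 0.1 s).
#' @param tr repetition time in seconds.
#' @param lagSearch candidate onset shifts in volumes (default
#'   \code{0:4}, i.e. 0-8 s of neural-to-BOLD delay).
#' @return An \linkS4class{HRFEstimate}.
#' @examples
#' ev <- simulateEventBold(300, 2, ttp = 6, noiseSd = 0, seed = 1)
#' est <- fitEventHrf(scale(ev$y)[, 1], ev$onsets, hrfBasisSet(), tr = 2,
#'                    lagSearch = 0)
#' ttp(est)
#' @export
fitEventHrf <- function(clean, events, basis = hrfBasisSet(), tr,
                        lagSearch = 0:4) {
  y <- as.numeric(clean)
  onsets <- if (is(events, "EventTrain")) events@onsets else
    as.integer(events)
  if (length(onsets) < 1L) stop("need at least one event")
  n <- length(y)
  B <- .basisAtTr(basis, tr)
  best <- NULL
  for (s in lagSearch) {
    o <- onsets - s
    o <- o[o >= 1L & o <= n]
    if (length(o) == 0L) next
    train <- numeric(n)
    train[o] <- train[o] + 1
    X <- cbind(apply(B, 2L, function(col) .causalConv(train, col)),
               intercept = 1)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("singular event design: events too dense for the basis")
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (is.null(best) || r2 > best$r2)
      best <- list(r2 = r2, beta = fit$coefficients, shift = s,
                   nEvents = length(o))
  }
  if (is.null(best)) stop("no admissible onset shift")
  beta <- best$beta
  kernel <- beta[1] * basis@canonical +
    beta[2] * basis@temporalDerivative +
    beta[3] * basis@dispersionDerivative
  dt <- basis@params@dt
  ttpHat <- (which.max(kernel) - 1L) * dt
  new("HRFEstimate", kernel = as.numeric(kernel), dt = dt, ttp = ttpHat,
      nEvents = as.integer(best$nEvents),
      basisBetas = unname(beta[1:3]), baseline = unname(beta[4]),
      fitR2 = max(0, min(1, best$r2)), onsetShift = best$shift * tr)
}

#' Wiener-filter recovery of the neural signal
#'
#' Regularized frequency-domain deconvolution:
#' \code{xhat = IFFT( Conj(H) * Y / (|H|^2 + lambda) )} with
#' \code{lambda = noiseFloor * max |H|^2}.
#'
#' @param y numeric observed series.
#' @param kernel \linkS4class{HRFKernel} sampled at the series' TR, or a
#'   numeric kernel on that grid.
#' @param noiseFloor positive regularization fraction of the peak squared
#'   gain.
#' @return A numeric series aligned to \code{y}.
#' @examples
#' ev <- simulateEventBold(150, 2, ttp = 5, noiseSd = 0, seed = 2)
#' xhat <- wienerRecoverNeural(ev$y, ev$kernel, 1e-8)
#' @export
wienerRecoverNeural <- function(y, kernel, noiseFloor = 0.01) {
  if (noiseFloor <= 0) stop("noiseFloor must be positive")
  k <- if (is(kernel, "HRFKernel")) kernel@samples else as.numeric(kernel)
  if (all(k == 0)) stop("degenerate kernel")
  y <- as.numeric(y)
  n <- length(y)
  H <- stats::fft(c(k, numeric(max(0L, n - length(k))))[seq_len(n)])
  Y <- stats::fft(y)
  lambda <- noiseFloor * max(Mod(H)^2)
  Xhat <- Conj(H) * Y / (Mod(H)^2 + lambda)
  Re(stats::fft(Xhat, inverse = TRUE)) / n
}

#' Region- and participant-specific HRF from concatenated sessions
#'
#' Cleans each session independently, concatenates the standardized
#' residuals, detects pseudo-events on the concatenation (dropping any
#' onset within a guard interval of a session seam, where the convolution
#' would leak across sessions), and fits the three-function basis.
#'
#' @param boldSessions list of numeric ROI series, one per session.
#' @param nuisanceSessions list of \linkS4class{NuisanceDesign} (or
#'   matrices), or \code{NULL}.
#' @param tr repetition time in seconds.
#' @param basis an \linkS4class{HRFBasisSet}.
#' @param k event threshold in SD units.
#' @param lagSearch candidate onset shifts in volumes.
#' @param guard seconds around each seam within which events are dropped
#'   (default 32, the kernel length).
#' @param cutoff high-pass cut-off period in seconds.
#' @return An \linkS4class{HRFEstimate}.
#' @examples
#' ev1 <- simulateEventBold(150, 2, ttp = 5, noiseSd = 0.2, seed = 3)
#' ev2 <- simulateEventBold(150, 2, ttp = 5, noiseSd = 0.2, seed = 4)
#' est <- estimateRoiHrf(list(ev1$y, ev2$y), NULL, tr = 2)
#' ttp(est)
#' @export
estimateRoiHrf <- function(boldSessions, nuisanceSessions = NULL, tr,
                           basis = hrfBasisSet(), k = 1, lagSearch = 0:4,
                           guard = 32, cutoff = 128) {
  nSess <- length(boldSessions)
  stopifnot(nSess >= 1L)
  cleaned <- lapply(seq_len(nSess), function(s) {
    cleanSignal(boldSessions[[s]],
                if (!is.null(nuisanceSessions)) nuisanceSessions[[s]],
                tr = tr, cutoff = cutoff)
  })
  lens <- vapply(cleaned, length, integer(1))
  concat <- unlist(cleaned, use.names = FALSE)
  train <- detectPseudoEvents(concat, k = k)
  onsets <- train@onsets
  if (nSess > 1L) {
    seams <- cumsum(lens)[-nSess] + 0.5       # between volumes m and m+1
    guardVol <- guard / tr
    nearSeam <- vapply(onsets, function(o)
      any(abs(o - seams) < guardVol), logical(1))
    onsets <- onsets[!nearSeam]
    if (length(onsets) == 0L)
      stop("all events fell inside the seam guard: estimation impossible")
  }
  fitEventHrf(concat, onsets, basis = basis, tr = tr,
              lagSearch = lagSearch)
}
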