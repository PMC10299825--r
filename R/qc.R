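#' @include AllClasses.R utils.R coupling.R groupstats.R
NULL

#' Temporal signal-to-noise ratio
#'
#' Mean over SD of a BOLD time series.  For a voxel-by-time matrix the
#' voxelwise tSNR is computed first and then averaged (the ROI
#' convention); a single series gives its own mean/SD ratio.  tSNR is
#' invariant to multiplicative rescaling.
#'
#' @param x numeric series, or a voxels x time matrix.
#' @return Numeric tSNR (\code{+Inf} with a warning for a constant
#'   series).
#' @examples
#' temporalSnr(rnorm(150, mean = 100, sd = 2))
#' @export
temporalSnr <- function(x) {
  one <- function(v) {
    s <- stats::sd(v)
    if (s == 0) {
      warning("constant series: tSNR reported as +Inf")
      return(Inf)
    }
    mean(v) / s
  }
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop("need at least two time points")
    mean(apply(x, 1L, one))
  } else {
    if (length(x) < 2L) stop("need at least two time points")
    one(as.numeric(x))
  }
}

#' Contrast-to-noise ratio of a target region
#'
#' Relative intensity difference of a target region (e.g. the locus
#' coeruleus on a neuromelanin-sensitive image) versus a reference
#' region: \code{(roi - reference) / reference}.
#'
#' @param meanRoiIntensity mean intensity inside the target region.
#' @param meanReferenceIntensity mean intensity of the (positive)
#'   reference region.
#' @return Numeric CNR.
#' @examples
#' lcCnr(117, 100)
#' @export
lcCnr <- function(meanRoiIntensity, meanReferenceIntensity) {
  if (any(meanReferenceIntensity <= 0))
    stop("reference intensity must be positive")
  (meanRoiIntensity - meanReferenceIntensity) / meanReferenceIntensity
}

#' Pairwise partial correlations among nuclei, controlling a confound
#'
#' For every ROI pair of every participant, both series are residualized
#' on the confound series (with intercept) and correlated; the
#' per-participant coefficients are Fisher-z transformed and submitted to
#' one-sample t tests across participants, FDR-corrected over pairs.
#'
#' @param roiSeriesList list over participants of cleaned, demeaned
#'   volumes x ROIs matrices (shared column names).
#' @param confoundList list over participants of numeric confound series
#'   (e.g. the pontine control region).
#' @return A list: \code{meanZ} (symmetric ROI x ROI matrix of mean
#'   Fisher-z partial correlations, diagonal \code{NA}) and \code{tests}
#'   (data.frame per pair: \code{t}, \code{p}, \code{p_fdr}).
#' @examples
#' mk <- function(seed) { set.seed(seed); matrix(rnorm(300), 150, 2,
#'   dimnames = list(NULL, c("a", "b"))) }
#' res <- aasPartialCorrelationMatrix(lapply(1:6, mk),
#'                                    lapply(7:12, function(s) rnorm(150)))
#' res$tests
#' @export
aasPartialCorrelationMatrix <- function(roiSeriesList, confoundList) {
  nP <- length(roiSeriesList)
  stopifnot(nP == length(confoundList), nP >= 2L)
  rois <- colnames(roiSeriesList[[1]])
  if (is.null(rois)) stop("ROI matrices must carry column names")
  pairs <- utils::combn(rois, 2L)
  zMat <- matrix(NA_real_, length(rois), length(rois),
                 dimnames = list(rois, rois))
  tests <- NULL
  zStore <- matrix(NA_real_, nP, ncol(pairs))
  for (p in seq_len(nP)) {
    m <- roiSeriesList[[p]]
    g <- as.numeric(confoundList[[p]])
    if (stats::sd(g) == 0) stop("constant confound series")
    X <- cbind(1, g)
    res <- apply(m[, rois, drop = FALSE], 2L,
                 function(col) stats::residuals(stats::lm.fit(X, col)))
    for (j in seq_len(ncol(pairs))) {
      r <- stats::cor(res[, pairs[1, j]], res[, pairs[2, j]])
      zStore[p, j] <- fisherZ(r)
    }
  }
  for (j in seq_len(ncol(pairs))) {
    tt <- oneSampleTTest(zStore[, j])
    tests <- rbind(tests, data.frame(
      roi1 = pairs[1, j], roi2 = pairs[2, j],
      meanZ = mean(zStore[, j]), t = tt$t, p = tt$p))
    zMat[pairs[1, j], pairs[2, j]] <- mean(zStore[, j])
    zMat[pairs[2, j], pairs[1, j]] <- mean(zStore[, j])
  }
  tests$p_fdr <- fdrAdjust(tests$p)
  list(meanZ = zMat, tests = tests)
}
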