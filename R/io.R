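#' @include AllClasses.R simulate.R pupil.R nuisance.R glm.R deconvolve.R
#' @include coupling.R groupstats.R qc.R
NULL

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.delim(path, check.names = FALSE)
}

#' Write one session to disk
#'
#' Emits the package's plain-text interchange files for a session bundle:
#' \code{pupil.tsv} (time_s, diameter, valid), \code{physio.tsv} (time_s,
#' pulse, resp; common grid), \code{motion.tsv} (6 columns),
#' \code{bold.tsv} (volume plus one column per ROI),
#' \code{ventricle.tsv} and \code{truth.json}.
#'
#' @param session a session bundle as produced by
#'   \code{\link{simulateSession}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$pupil
  .writeTsv(data.frame(time_s = tr@time, diameter = tr@diameter,
                       valid = as.integer(tr@valid)),
            file.path(dir, "pupil.tsv"))
  ph <- session$physio
  tt <- (seq_along(ph@pulse) - 1) / ph@pulseRate
  .writeTsv(data.frame(time_s = tt, pulse = ph@pulse, resp = ph@resp),
            file.path(dir, "physio.tsv"))
  .writeTsv(as.data.frame(session$motion), file.path(dir, "motion.tsv"))
  bold <- as.data.frame(session$bold@series)
  bold <- cbind(volume = seq_len(nrow(bold)), bold)
  .writeTsv(bold, file.path(dir, "bold.tsv"))
  .writeTsv(data.frame(ventricle = session$ventricle),
            file.path(dir, "ventricle.tsv"))
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(c(pupil = file.path(dir, "pupil.tsv"),
              physio = file.path(dir, "physio.tsv"),
              motion = file.path(dir, "motion.tsv"),
              bold = file.path(dir, "bold.tsv"),
              ventricle = file.path(dir, "ventricle.tsv"),
              truth = file.path(dir, "truth.json")))
}

#' Read one session from disk
#'
#' Reads the interchange files written by \code{\link{writeSession}},
#' validates sampling metadata and alignment, and rebuilds the session
#' bundle.
#'
#' @param dir session directory.
#' @param pupilRate expected pupil sampling rate in Hz (default 250).
#' @param tr expected repetition time in seconds (default 2).
#' @return A session bundle (list) mirroring
#'   \code{\link{simulateSession}} output (without \code{smooth}).
#' @export
readSession <- function(dir, pupilRate = 250, tr = 2) {
  pup <- .readTsv(file.path(dir, "pupil.tsv"))
  for (col in c("time_s", "diameter", "valid"))
    if (!col %in% names(pup))
      stop("pupil.tsv is missing column '", col, "'")
  step <- stats::median(diff(pup$time_s))
  if (abs(step - 1 / pupilRate) > 1e-6)
    stop(sprintf("pupil.tsv sampling step %.6f s does not match %g Hz",
                 step, pupilRate))
  trace <- pupilTrace(time = pup$time_s, diameter = pup$diameter,
                      valid = as.logical(pup$valid), rate = pupilRate)
  phy <- .readTsv(file.path(dir, "physio.tsv"))
  for (col in c("time_s", "pulse", "resp"))
    if (!col %in% names(phy))
      stop("physio.tsv is missing column '", col, "'")
  fs <- 1 / stats::median(diff(phy$time_s))
  physio <- new("PhysioRecording", pulse = phy$pulse, resp = phy$resp,
                pulseRate = fs, respRate = fs, cardiacPeaks = numeric())
  motion <- as.matrix(.readTsv(file.path(dir, "motion.tsv")))
  boldDf <- .readTsv(file.path(dir, "bold.tsv"))
  roiCols <- setdiff(names(boldDf), "volume")
  series <- as.matrix(boldDf[, roiCols, drop = FALSE])
  nVol <- nrow(series)
  if (nrow(motion) != nVol)
    stop(sprintf("alignment error: motion has %d rows but BOLD %d volumes",
                 nrow(motion), nVol))
  expect <- nVol * tr * pupilRate
  if (nrow(pup) < expect)
    stop(sprintf("truncated pupil file: %d samples but %d needed",
                 nrow(pup), expect))
  ventricle <- .readTsv(file.path(dir, "ventricle.tsv"))$ventricle
  if (length(ventricle) != nVol)
    stop("alignment error: ventricle series does not match the volumes")
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  list(pupil = trace, physio = physio, motion = motion,
       bold = new("VolumeSeries", series = series, tr = tr),
       ventricle = ventricle, truth = truth)
}

#' Write a whole study to disk
#'
#' One directory per session plus \code{manifest.tsv},
#' \code{manifest.json}, the per-participant ground-truth table and the
#' generating configuration.
#'
#' @param study study list from \code{\link{simulateStudy}}.
#' @param dir output directory.
#' @param cfg the generating \linkS4class{SimulationConfig} (stored for
#'   provenance).
#' @return Invisibly, \code{dir}.
#' @export
writeStudy <- function(study, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$sessions))
    writeSession(study$sessions[[id]], file.path(dir, id))
  .writeTsv(study$manifest, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeTsv(study$participants, file.path(dir, "participants.tsv"))
  if (!is.null(cfg)) {
    cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
    names(cfgList) <- slotNames(cfg)
    jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a study from disk
#'
#' @param dir study directory written by \code{\link{writeStudy}}.
#' @param pupilRate,tr expected sampling metadata.
#' @return A study list (\code{manifest}, \code{sessions},
#'   \code{participants}) mirroring \code{\link{simulateStudy}}.
#' @export
readStudy <- function(dir, pupilRate = 250, tr = 2) {
  manifest <- .readTsv(file.path(dir, "manifest.tsv"))
  manifest$exclusionReason[is.na(manifest$exclusionReason)] <- ""
  sessions <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    sessions[[id]] <- readSession(file.path(dir, id),
                                  pupilRate = pupilRate, tr = tr)
  }
  partPath <- file.path(dir, "participants.tsv")
  participants <- if (file.exists(partPath)) .readTsv(partPath) else NULL
  list(manifest = manifest, sessions = sessions,
       participants = participants)
}

#' Average a 4-D image over a mask
#'
#' Unweighted mean over mask voxels per volume; no smoothing.
#'
#' @param img4d 4-D numeric array (x, y, z, volumes).
#' @param mask 3-D logical/numeric array on the same grid.
#' @return Numeric series, one value per volume.
#' @examples
#' img <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
#' mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
#' extractRoiSeries(img, mask)
#' @export
extractRoiSeries <- function(img4d, mask) {
  stopifnot(length(dim(img4d)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(img4d)[1:3] == dim(mask)))
    stop("image and mask grids do not match")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("empty mask")
  nVol <- dim(img4d)[4]
  flat <- matrix(img4d, ncol = nVol)
  colMeans(flat[idx, , drop = FALSE])
}

## pupil QC + regressors for all included sessions of one participant
.participantPrep <- function(sessIds, sessions, tr, nVolumes, shift) {
  bold <- list(); size <- list(); deriv <- list(); nuis <- list()
  qc <- NULL
  for (id in sessIds) {
    sess <- sessions[[id]]
    qcRes <- qcInvalidFraction(sess$pupil)
    qc <- rbind(qc, data.frame(id = id, invalidFraction = qcRes$fraction,
                               include = qcRes$include))
    if (!qcRes$include) next
    bold[[id]] <- sess$bold
    size[[id]] <- preprocessPupil(sess$pupil, "size", shift = shift,
                                  tr = tr, nVolumes = nVolumes)
    deriv[[id]] <- preprocessPupil(sess$pupil, "derivative",
                                   shift = shift, tr = tr,
                                   nVolumes = nVolumes)
    nuis[[id]] <- buildNuisanceDesign(sess$physio, sess$motion,
                                      sess$ventricle, nVolumes, tr)
  }
  list(bold = bold, size = size, deriv = deriv, nuis = nuis, qc = qc)
}

#' Run the full analysis over a study
#'
#' Orchestrates the pipeline in the order quality control, blind HRF
#' estimation, TTP sweep, lagged cross-correlation, cross-spectral
#' density, then group statistics, writing tidy TSV tables into
#' \code{qc/}, \code{hrf/}, \code{sweep/}, \code{xcorr/}, \code{csd/} and
#' \code{group/} under \code{outDir} together with a provenance JSON.
#' Participants whose processing fails are quarantined and listed; the
#' run continues.
#'
#' @param study study list (from \code{\link{simulateStudy}} or
#'   \code{\link{readStudy}}).
#' @param outDir output directory; \code{NULL} skips writing.
#' @param tr repetition time in seconds.
#' @param shift pupil shift in seconds (default 1).
#' @param ttpGrid TTP sweep grid (default \code{1:6}).
#' @param maxLag,lagStep cross-correlation lag grid in seconds.
#' @param csdWindow,csdOverlap Welch segmentation (samples).
#' @param estimateHrf run the blind per-ROI HRF estimation (default
#'   \code{TRUE}; the slowest stage).
#' @param seed seed recorded in the provenance (analysis itself is
#'   deterministic).
#' @return A list of result tables: \code{qc}, \code{tsnr}, \code{hrf},
#'   \code{sweep}, \code{xcorr}, \code{csd}, \code{groupSweep},
#'   \code{groupXcorr}, \code{anovaTtp}, \code{failures}.
#' @export
runStudy <- function(study, outDir = NULL, tr = 2, shift = 1,
                     ttpGrid = 1:6, maxLag = 8, lagStep = 2,
                     csdWindow = 10, csdOverlap = 3, estimateHrf = TRUE,
                     seed = 1) {
  manifest <- study$manifest
  manifest <- manifest[manifest$included %in% c(TRUE, 1), , drop = FALSE]
  participants <- unique(manifest$participant)
  nVolumes <- nrow(study$sessions[[manifest$id[1]]]$bold@series)
  rois <- colnames(study$sessions[[manifest$id[1]]]$bold@series)
  qcTab <- NULL; tsnrTab <- NULL; hrfTab <- NULL; sweepTab <- NULL
  xcorrTab <- NULL; csdTab <- NULL; failures <- NULL
  for (pid in participants) {
    res <- tryCatch({
      ids <- manifest$id[manifest$participant == pid]
      prep <- .participantPrep(ids, study$sessions, tr, nVolumes, shift)
      if (length(prep$bold) == 0L) stop("no usable session after pupil QC")
      qcLocal <- cbind(participant = pid, prep$qc)
      tsnrLocal <- NULL
      for (id in names(prep$bold)) for (roi in rois)
        tsnrLocal <- rbind(tsnrLocal, data.frame(
          participant = pid, id = id, roi = roi,
          tsnr = temporalSnr(prep$bold[[id]]@series[, roi])))
      sweepLocal <- cbind(participant = pid,
        ttpSweep(prep$bold, prep$size, prep$deriv, prep$nuis, tr,
                 ttpGrid))
      xcorrLocal <- NULL; csdLocal <- NULL; hrfLocal <- NULL
      for (roi in rois) {
        cleanSess <- lapply(names(prep$bold), function(id)
          cleanSignal(prep$bold[[id]]@series[, roi], prep$nuis[[id]],
                      tr, ar1 = FALSE))
        zSum <- 0; csdSum <- NULL; freqs <- NULL
        for (s in seq_along(cleanSess)) {
          xc <- crossCorrelateLags(prep$size[[s]], cleanSess[[s]], tr,
                                   maxLag, lagStep)
          zSum <- zSum + xc$z
          cs <- crossSpectralDensity(regressorValues(prep$size[[s]]),
                                     cleanSess[[s]], tr, csdWindow,
                                     csdOverlap)
          freqs <- cs$frequency_hz
          csdSum <- if (is.null(csdSum)) cs$cross_power else
            csdSum + cs$cross_power
        }
        lags <- seq(-maxLag, maxLag, by = lagStep)
        xcorrLocal <- rbind(xcorrLocal, data.frame(
          participant = pid, roi = roi, lag_s = lags,
          z = zSum / length(cleanSess)))
        csdLocal <- rbind(csdLocal, data.frame(
          participant = pid, roi = roi, frequency_hz = freqs,
          cross_power = csdSum / length(cleanSess)))
        if (estimateHrf) {
          est <- tryCatch(
            estimateRoiHrf(lapply(names(prep$bold), function(id)
              prep$bold[[id]]@series[, roi]),
              prep$nuis[names(prep$bold)], tr),
            error = function(e) NULL)
          if (!is.null(est))
            hrfLocal <- rbind(hrfLocal, data.frame(
              participant = pid, roi = roi, ttp_s = est@ttp,
              n_events = est@nEvents, fit_r2 = est@fitR2))
        }
      }
      list(qc = qcLocal, tsnr = tsnrLocal, sweep = sweepLocal,
           xcorr = xcorrLocal, csd = csdLocal, hrf = hrfLocal)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(participant = pid,
                                             error = conditionMessage(res)))
      next
    }
    qcTab <- rbind(qcTab, res$qc); tsnrTab <- rbind(tsnrTab, res$tsnr)
    sweepTab <- rbind(sweepTab, res$sweep)
    xcorrTab <- rbind(xcorrTab, res$xcorr)
    csdTab <- rbind(csdTab, res$csd); hrfTab <- rbind(hrfTab, res$hrf)
  }
  groupSweep <- NULL; anovaTtp <- NULL; groupXcorr <- NULL
  if (!is.null(sweepTab)) {
    sz <- sweepTab[sweepTab$variant == "size" & is.finite(sweepTab$t), ]
    tb <- data.frame(participant = sz$participant,
                     condition = paste(sz$roi, sz$ttp, sep = ":"),
                     value = sz$t, roi = sz$roi)
    groupSweep <- groupConditionTable(tb, familyBy = "roi")
    for (roi in rois) {
      subt <- sz[sz$roi == roi, , drop = FALSE]
      m <- tapply(subt$t, list(subt$participant, subt$ttp), mean)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) >= 2) {
        an <- tryCatch(rmAnovaMainEffect(m), error = function(e) NULL)
        if (!is.null(an))
          anovaTtp <- rbind(anovaTtp, data.frame(roi = roi, F = an$F,
                                                 p = an$p))
      }
    }
    if (!is.null(anovaTtp)) anovaTtp$p_fdr <- fdrAdjust(anovaTtp$p)
  }
  if (!is.null(xcorrTab)) {
    tb <- data.frame(participant = xcorrTab$participant,
                     condition = paste(xcorrTab$roi, xcorrTab$lag_s,
                                       sep = ":"),
                     value = xcorrTab$z, roi = xcorrTab$roi)
    groupXcorr <- groupConditionTable(tb, familyBy = "roi")
  }
  out <- list(qc = qcTab, tsnr = tsnrTab, hrf = hrfTab, sweep = sweepTab,
              xcorr = xcorrTab, csd = csdTab, groupSweep = groupSweep,
              groupXcorr = groupXcorr, anovaTtp = anovaTtp,
              failures = failures)
  if (!is.null(outDir)) {
    for (sub in c("qc", "hrf", "sweep", "xcorr", "csd", "group"))
      dir.create(file.path(outDir, sub), recursive = TRUE,
                 showWarnings = FALSE)
    if (!is.null(qcTab)) .writeTsv(qcTab, file.path(outDir, "qc",
                                                    "pupil_qc.tsv"))
    if (!is.null(tsnrTab)) .writeTsv(tsnrTab,
                                     file.path(outDir, "qc", "tsnr.tsv"))
    if (!is.null(hrfTab)) .writeTsv(hrfTab,
                                    file.path(outDir, "hrf",
                                              "hrf_summary.tsv"))
    if (!is.null(sweepTab)) .writeTsv(sweepTab,
                                      file.path(outDir, "sweep",
                                                "ttp_sweep.tsv"))
    if (!is.null(xcorrTab)) .writeTsv(xcorrTab,
                                      file.path(outDir, "xcorr",
                                                "crosscorr.tsv"))
    if (!is.null(csdTab)) .writeTsv(csdTab,
                                    file.path(outDir, "csd", "csd.tsv"))
    if (!is.null(groupSweep)) .writeTsv(groupSweep,
                                        file.path(outDir, "group",
                                                  "sweep_group.tsv"))
    if (!is.null(groupXcorr)) .writeTsv(groupXcorr,
                                        file.path(outDir, "group",
                                                  "xcorr_group.tsv"))
    if (!is.null(anovaTtp)) .writeTsv(anovaTtp,
                                      file.path(outDir, "group",
                                                "ttp_anova.tsv"))
    if (!is.null(failures)) .writeTsv(failures,
                                      file.path(outDir, "failures.tsv"))
    prov <- list(seed = seed, tr = tr, shift = shift, ttpGrid = ttpGrid,
                 maxLag = maxLag, lagStep = lagStep,
                 csdWindow = csdWindow, csdOverlap = csdOverlap,
                 nParticipants = length(participants),
                 rVersion = as.character(getRversion()),
                 package = as.character(utils::packageVersion("pupilAAS")))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
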