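#' @include AllClasses.R utils.R
NULL

## Padding (seconds) of the internally generated smooth signal on each side
## of the session window, so that lags and HRF convolutions use real samples
## instead of zero padding.  32 s matches the kernel length default.
.SIM_PAD <- 32

## Common sampling rate (Hz) of the simulated pulse and respiration traces.
.PHYSIO_RATE <- 50

#' Build a synthetic-session configuration
#'
#' Constructor for \linkS4class{SimulationConfig}.  Defaults emulate the
#' targeted acquisition: 5-minute resting-state sessions at TR = 2 s
#' (150 volumes), pupil at 250 Hz with blink gaps, slow pupil oscillations
#' in 0.04-0.1 Hz, cardiac activity near 1 Hz and respiration near 0.3 Hz.
#'
#' @param duration session length in seconds.
#' @param pupilRate pupil sampling rate in Hz.
#' @param tr repetition time in seconds.
#' @param nRois number of simulated ROIs.
#' @param couplingMode \code{"lag"}, \code{"hrf"} or \code{"none"}.
#' @param couplingLag lag (seconds, multiple of \code{tr}) between pupil and
#'   BOLD in \code{"lag"} mode; negative = pupil precedes BOLD.
#' @param couplingTtp delay-of-response parameter of the transfer HRF in
#'   \code{"hrf"} mode (seconds); may be a vector recycled over ROIs.
#' @param couplingGain amplitude of the coupled component.
#' @param boldNoiseSd SD of white noise added to each ROI series.
#' @param physioBleed amplitude of aliased cardiac/respiratory sinusoids
#'   added to each ROI series.
#' @param pupilLag physiological delay (seconds) of the pupil behind the
#'   neural signal driving it (default 1; the preprocessing shift of the
#'   same magnitude compensates it).
#' @param blinkRate blink events per minute.
#' @param oscBand two-element band (Hz) of the smooth pupil signal.
#' @param heartRate beats per minute.
#' @param respRate breaths per minute.
#' @param seed integer RNG seed; fully determines all generator output.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(couplingMode = "lag", couplingLag = -4, seed = 7)
#' @export
simulationConfig <- function(duration = 300, pupilRate = 250, tr = 2,
                             nRois = 3, couplingMode = c("lag", "hrf", "none"),
                             couplingLag = 0, couplingTtp = 6,
                             couplingGain = 1, boldNoiseSd = 0.5,
                             physioBleed = 0, pupilLag = 1, blinkRate = 15,
                             oscBand = c(0.04, 0.1), heartRate = 60,
                             respRate = 18, seed = 1) {
  couplingMode <- match.arg(couplingMode)
  cfg <- new("SimulationConfig", duration = duration, pupilRate = pupilRate,
             tr = tr, nRois = as.integer(nRois), couplingMode = couplingMode,
             couplingLag = couplingLag, couplingTtp = couplingTtp,
             couplingGain = couplingGain, boldNoiseSd = boldNoiseSd,
             physioBleed = physioBleed, pupilLag = pupilLag,
             blinkRate = blinkRate,
             oscBand = oscBand, heartRate = heartRate, respRate = respRate,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

## Smooth band-limited signal over the padded window, at the native pupil
## rate plus its TR-bin means.  Gaussian noise is band-passed with a
## 4th-order Butterworth filter at a decimated rate (the band edges are far
## below the 250 Hz Nyquist, where a direct high-rate digital filter would
## be numerically degenerate), standardized, and interpolated back to the
## native grid.  Consumes RNG state; no seed handling here.
.smoothPupilCore <- function(cfg) {
  pad <- .SIM_PAD
  total <- cfg@duration + 2 * pad
  fsLow <- 2                               # decimated filtering rate (Hz)
  ## extra settle-in tail discarded after filtering
  settle <- 200
  nLow <- ceiling((total + 2 * settle) * fsLow)
  wn <- cfg@oscBand / (fsLow / 2)
  bf <- signal::butter(4, wn, type = "pass")
  z <- signal::filtfilt(bf, stats::rnorm(nLow))
  tLow <- (seq_len(nLow) - 1) / fsLow - settle - pad
  keep <- tLow >= -pad - 1 & tLow <= cfg@duration + pad + 1
  z <- .zscore(z[keep])
  tLow <- tLow[keep]
  tHigh <- seq(-pad, cfg@duration + pad - 1 / cfg@pupilRate,
               by = 1 / cfg@pupilRate)
  smooth <- stats::spline(tLow, z, xout = tHigh)$y
  ## TR-bin means over the padded grid
  spv <- round(cfg@pupilRate * cfg@tr)
  nBins <- length(smooth) %/% spv
  neural <- colMeans(matrix(smooth[seq_len(nBins * spv)], nrow = spv))
  list(timeHigh = tHigh, smooth = smooth, neuralPadded = neural,
       padVolumes = as.integer(pad / cfg@tr))
}

## pupil signal in the session window: the smooth neural signal delayed by
## the physiological pupil lag
.pupilInWindow <- function(cfg, core) {
  idx <- which(core$timeHigh >= 0 & core$timeHigh < cfg@duration)
  lagSamp <- as.integer(round(cfg@pupilLag * cfg@pupilRate))
  core$smooth[idx - lagSamp]
}

## Insert Poisson blinks; returns trace components.  Consumes RNG state.
.insertBlinks <- function(cfg, tt, pupilVals, baseline = 5,
                          floorValue = 0) {
  diam <- baseline + pupilVals
  valid <- rep(TRUE, length(tt))
  nBlinks <- stats::rpois(1L, cfg@blinkRate * cfg@duration / 60)
  if (nBlinks > 0) {
    onsets <- sort(stats::runif(nBlinks, 0, cfg@duration))
    durs <- stats::runif(nBlinks, 0.1, 0.4)
    n <- length(tt)
    for (i in seq_len(nBlinks)) {
      a <- max(1L, ceiling(onsets[i] * cfg@pupilRate) + 1L)
      b <- min(n, floor((onsets[i] + durs[i]) * cfg@pupilRate) + 1L)
      if (a > b) next
      diam[a:b] <- floorValue
      valid[a:b] <- FALSE
    }
  }
  list(time = tt, diameter = diam, valid = valid)
}

#' Simulate a pupil trace with known smooth ground truth
#'
#' Generates a band-limited smooth pupil signal (filtered Gaussian noise in
#' \code{oscBand}, standardized), adds a constant baseline, and inserts
#' Poisson-distributed blink gaps during which the trace drops to a floor
#' value and is flagged invalid.  The smooth signal before blink insertion
#' and its TR-bin means (the "neural" signal driving coupled BOLD) are
#' returned as ground truth.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A list: \code{trace} (\linkS4class{PupilTrace}), \code{smooth}
#'   (numeric, the pre-blink smooth signal on the trace grid), and
#'   \code{neural} (numeric, TR-bin means over the session window).
#' @examples
#' sim <- simulatePupil(simulationConfig(seed = 1))
#' sim$trace
#' @export
simulatePupil <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  core <- .smoothPupilCore(cfg)
  tWin <- core$timeHigh[core$timeHigh >= 0 & core$timeHigh < cfg@duration]
  pupilVals <- .pupilInWindow(cfg, core)
  blinked <- .insertBlinks(cfg, tWin, pupilVals)
  trace <- new("PupilTrace", time = blinked$time,
               diameter = blinked$diameter, valid = blinked$valid,
               rate = cfg@pupilRate,
               rawInvalidFraction = mean(!blinked$valid),
               provenance = list("simulated"))
  nVol <- as.integer(cfg@duration / cfg@tr)
  pad <- core$padVolumes
  list(trace = trace, smooth = 5 + pupilVals,
       neural = core$neuralPadded[pad + seq_len(nVol)])
}

## Cardiac peak train and traces.  Consumes RNG state.
.physioCore <- function(cfg) {
  fs <- .PHYSIO_RATE
  if (cfg@heartRate / 60 >= fs / 2)
    stop("heartRate at or above the Nyquist frequency of the pulse trace")
  if (cfg@respRate / 60 >= fs / 2)
    stop("respRate at or above the Nyquist frequency of the belt trace")
  ibi <- 60 / cfg@heartRate
  nBeats <- ceiling(cfg@duration / ibi) + 8L
  ibis <- ibi * (1 + 0.02 * stats::rnorm(nBeats))
  peaks <- cumsum(ibis) - ibis[1] / 2
  peaks <- peaks[peaks > 0.2 & peaks < cfg@duration - 0.05]
  tt <- seq(0, cfg@duration - 1 / fs, by = 1 / fs)
  ## pulse: narrow Gaussian systolic bumps at the peak times
  pulse <- rep(0, length(tt))
  nT <- length(tt)
  for (p in peaks) {
    a <- max(1L, floor((p - 0.3) * fs) + 1L)
    b <- min(nT, ceiling((p + 0.3) * fs) + 1L)
    pulse[a:b] <- pulse[a:b] + exp(-((tt[a:b] - p)^2) / (2 * 0.05^2))
  }
  ## respiration: sinusoid with slow amplitude modulation
  fr <- cfg@respRate / 60
  phase <- stats::runif(2, 0, 2 * pi)
  amp <- 1 + 0.2 * sin(2 * pi * 0.01 * tt + phase[2])
  resp <- amp * sin(2 * pi * fr * tt + phase[1])
  new("PhysioRecording", pulse = pulse, resp = resp, pulseRate = fs,
      respRate = fs, cardiacPeaks = peaks)
}

#' Simulate pulse and respiration traces
#'
#' Pulse is a train of narrow systolic bumps at slightly jittered beat
#' times near \code{heartRate}; respiration is a sinusoid near
#' \code{respRate} with slow (0.01 Hz) amplitude modulation.  Ground-truth
#' beat times are stored in the \code{cardiacPeaks} slot.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{PhysioRecording}.
#' @examples
#' rec <- simulatePhysio(simulationConfig(seed = 2))
#' length(cardiacPeakTimes(rec))
#' @export
simulatePhysio <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed + 1L)
  .physioCore(cfg)
}

## BOLD from the padded neural signal.  Consumes RNG state.
.boldCore <- function(cfg, neuralPadded, padVolumes) {
  nVol <- as.integer(cfg@duration / cfg@tr)
  tVol <- (seq_len(nVol) - 1) * cfg@tr + cfg@tr / 2
  ttps <- rep_len(cfg@couplingTtp, cfg@nRois)
  series <- matrix(0, nVol, cfg@nRois,
                   dimnames = list(NULL, paste0("roi", seq_len(cfg@nRois))))
  truth <- list(trueLag = NA_real_, trueTtp = NA_real_,
                neuralSignal = neuralPadded[padVolumes + seq_len(nVol)],
                eventOnsets = numeric(), coupledRoiIds = character())
  for (j in seq_len(cfg@nRois)) {
    base <- switch(cfg@couplingMode,
      lag = {
        lagVol <- as.integer(round(cfg@couplingLag / cfg@tr))
        cfg@couplingGain *
          neuralPadded[padVolumes + seq_len(nVol) + lagVol]
      },
      hrf = {
        kern <- doubleGammaHrf(hrfParameters(p1 = ttps[j], dt = cfg@tr))
        conv <- .causalConv(neuralPadded, kernelSamples(kern))
        cfg@couplingGain * conv[padVolumes + seq_len(nVol)]
      },
      none = rep(0, nVol))
    bleed <- if (cfg@physioBleed > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      cfg@physioBleed * (sin(2 * pi * cfg@heartRate / 60 * tVol + ph[1]) +
                         sin(2 * pi * cfg@respRate / 60 * tVol + ph[2]))
    } else 0
    series[, j] <- base + bleed + cfg@boldNoiseSd * stats::rnorm(nVol)
  }
  if (cfg@couplingMode != "none") {
    truth$coupledRoiIds <- colnames(series)
    if (cfg@couplingMode == "lag") truth$trueLag <- cfg@couplingLag
    if (cfg@couplingMode == "hrf") truth$trueTtp <- ttps
  }
  list(bold = new("VolumeSeries", series = series, tr = cfg@tr),
       truth = truth)
}

#' Simulate ROI BOLD series coupled to a pupil-linked neural signal
#'
#' Builds ROI-average BOLD at TR resolution from the smooth pupil-linked
#' neural signal: in \code{"lag"} mode \code{BOLD(t) = gain *
#' neural(t + lag) + noise} (negative lag = pupil precedes BOLD, the
#' convention of all coupling results); in \code{"hrf"} mode the neural
#' signal is convolved with a double-gamma kernel with the configured
#' time-to-peak; in \code{"none"} mode BOLD is noise (plus optional
#' physiological bleed) only.
#'
#' @param pupilSim output of \code{\link{simulatePupil}} run on the same
#'   configuration (the ground-truth neural signal is rebuilt from the
#'   configured seed, so \code{pupilSim} may also be omitted).
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A list: \code{bold} (\linkS4class{VolumeSeries}) and
#'   \code{truth} (ground-truth list with \code{trueLag}, \code{trueTtp},
#'   \code{neuralSignal}, \code{coupledRoiIds}).
#' @examples
#' cfg <- simulationConfig(couplingMode = "lag", couplingLag = -2,
#'                         boldNoiseSd = 0.2, seed = 3)
#' sim <- simulateBoldFromPupil(cfg = cfg)
#' sim$bold
#' @export
simulateBoldFromPupil <- function(pupilSim = NULL, cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  core <- .smoothPupilCore(cfg)
  set.seed(cfg@seed + 2L)
  .boldCore(cfg, core$neuralPadded, core$padVolumes)
}

#' Simulate one complete session
#'
#' Generates all per-session inputs of the analysis pipeline from one seed:
#' pupil trace (with ground-truth smooth signal), pulse/respiration traces,
#' six motion parameters (slow random walks), ROI BOLD coupled to the pupil
#' per the configuration, and a ventricle noise series.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{pupil} (\linkS4class{PupilTrace}),
#'   \code{smooth}, \code{physio} (\linkS4class{PhysioRecording}),
#'   \code{motion} (volumes x 6 matrix), \code{bold}
#'   (\linkS4class{VolumeSeries}), \code{ventricle} (numeric) and
#'   \code{truth} (ground-truth list, recorded before noise was added).
#' @examples
#' sess <- simulateSession(simulationConfig(seed = 11))
#' names(sess)
#' @export
simulateSession <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  nVol <- as.integer(cfg@duration / cfg@tr)
  set.seed(cfg@seed)
  core <- .smoothPupilCore(cfg)
  tWin <- core$timeHigh[core$timeHigh >= 0 & core$timeHigh < cfg@duration]
  pupilVals <- .pupilInWindow(cfg, core)
  blinked <- .insertBlinks(cfg, tWin, pupilVals)
  trace <- new("PupilTrace", time = blinked$time,
               diameter = blinked$diameter, valid = blinked$valid,
               rate = cfg@pupilRate,
               rawInvalidFraction = mean(!blinked$valid),
               provenance = list("simulated"))
  physio <- { set.seed(cfg@seed + 1L); .physioCore(cfg) }
  set.seed(cfg@seed + 2L)
  boldSim <- .boldCore(cfg, core$neuralPadded, core$padVolumes)
  set.seed(cfg@seed + 3L)
  motion <- apply(matrix(stats::rnorm(nVol * 6, sd = 0.02), nVol, 6), 2,
                  cumsum)
  colnames(motion) <- paste0("motion_", 1:6)
  ventricle <- stats::rnorm(nVol)
  list(pupil = trace, smooth = 5 + pupilVals, physio = physio,
       motion = motion, bold = boldSim$bold, ventricle = ventricle,
       truth = boldSim$truth)
}

#' Simulate an event-driven BOLD series
#'
#' Builds a cleaned-BOLD-like series as a Poisson train of neural events
#' convolved with a double-gamma kernel plus white noise, for validating
#' the blind HRF estimation chain against known ground truth.
#'
#' @param nVolumes number of volumes.
#' @param tr repetition time (seconds).
#' @param eventRate expected events per minute.
#' @param ttp delay-of-response parameter of the generating kernel.
#' @param noiseSd SD of added white noise (the noiseless event response has
#'   unit peak amplitude per event).
#' @param seed integer seed.
#' @return A list: \code{y} (numeric series), \code{onsets} (true event
#'   volume indices, 1-based) and \code{kernel}
#'   (\linkS4class{HRFKernel} sampled at the TR).
#' @examples
#' ev <- simulateEventBold(150, 2, eventRate = 6, ttp = 5, noiseSd = 0.2,
#'                         seed = 4)
#' length(ev$onsets)
#' @export
simulateEventBold <- function(nVolumes, tr, eventRate = 6, ttp = 5,
                              noiseSd = 0.2, seed = 1) {
  set.seed(as.integer(seed))
  p <- eventRate / 60 * tr
  train <- as.numeric(stats::runif(nVolumes) < p)
  onsets <- which(train > 0)
  kern <- doubleGammaHrf(hrfParameters(p1 = ttp, dt = tr))
  y <- .causalConv(train, kernelSamples(kern)) +
    noiseSd * stats::rnorm(nVolumes)
  list(y = y, onsets = onsets, kernel = kern)
}

#' Simulate a multi-participant study
#'
#' Generates \code{nParticipants} x \code{nSessions} sessions with
#' per-participant coupling parameters optionally jittered around the
#' configured values, and (optionally) writes every session to disk in the
#' package's TSV/JSON interchange format together with a study manifest.
#'
#' @param nParticipants number of participants.
#' @param nSessions sessions per participant (1 or 2).
#' @param cfg a \linkS4class{SimulationConfig}; its seed determines all
#'   per-session seeds.
#' @param dir output directory; if \code{NULL} the study is returned
#'   in-memory only.
#' @param ttpJitterSd SD of per-participant jitter on \code{couplingTtp}.
#' @param gainJitterSd SD of per-participant jitter on \code{couplingGain}.
#' @return A list: \code{manifest} (data.frame), \code{sessions} (named
#'   list of session bundles) and \code{participants} (per-participant
#'   true parameter table).
#' @examples
#' study <- simulateStudy(2, 1, simulationConfig(seed = 5))
#' study$manifest
#' @export
simulateStudy <- function(nParticipants, nSessions = 2, cfg,
                          dir = NULL, ttpJitterSd = 0, gainJitterSd = 0) {
  stopifnot(nSessions %in% c(1L, 2L))
  validObject(cfg)
  seeds <- .deriveSeeds(cfg@seed, nParticipants * nSessions + nParticipants)
  jitterSeeds <- seeds[seq_len(nParticipants)]
  sessSeeds <- matrix(seeds[-seq_len(nParticipants)], nParticipants,
                      nSessions)
  participants <- data.frame(participant = sprintf("sub%02d",
                                                   seq_len(nParticipants)),
                             trueTtp = NA_real_, trueLag = NA_real_,
                             trueGain = NA_real_)
  sessions <- list()
  manifest <- NULL
  for (i in seq_len(nParticipants)) {
    set.seed(jitterSeeds[i])
    ttp_i <- cfg@couplingTtp + ttpJitterSd * stats::rnorm(1)
    ttp_i <- max(ttp_i, 0.5)
    gain_i <- cfg@couplingGain + gainJitterSd * stats::rnorm(1)
    participants$trueTtp[i] <- ttp_i
    participants$trueLag[i] <- cfg@couplingLag
    participants$trueGain[i] <- gain_i
    for (s in seq_len(nSessions)) {
      cfgI <- cfg
      cfgI@couplingTtp <- ttp_i
      cfgI@couplingGain <- gain_i
      cfgI@seed <- sessSeeds[i, s]
      sess <- simulateSession(cfgI)
      id <- sprintf("%s_ses%d", participants$participant[i], s)
      sessions[[id]] <- sess
      manifest <- rbind(manifest, data.frame(
        participant = participants$participant[i], session = s,
        id = id, seed = sessSeeds[i, s], included = TRUE,
        exclusionReason = ""))
    }
  }
  study <- list(manifest = manifest, sessions = sessions,
                participants = participants)
  if (!is.null(dir)) writeStudy(study, dir, cfg)
  study
}
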