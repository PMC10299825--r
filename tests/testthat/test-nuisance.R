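test_that("cardiac peak detection recovers the generated beats", {
  cfg <- simulationConfig(seed = 13, heartRate = 60)
  rec <- simulatePhysio(cfg)
  got <- detectCardiacPeaks(rec)
  expect_true(abs(length(got) - 300) <= 2)
  ## each detected peak within one sample of a ground-truth beat
  truth <- cardiacPeakTimes(rec)
  nearest <- vapply(got, function(p) min(abs(truth - p)), numeric(1))
  expect_true(all(nearest <= 1 / rec@pulseRate + 1e-9))
  expect_error(detectCardiacPeaks(rep(1, 1000), rate = 50), "flat-line")
})

test_that("cardiac phase follows the closed form", {
  peaks <- 0:10
  expect_equal(cardiacPhase(3, peaks), 0)
  expect_equal(cardiacPhase(3.5, peaks), pi)
  expect_equal(cardiacPhase(0.25, peaks), pi / 2)
  ## extrapolation outside the peak range stays finite
  expect_true(is.finite(cardiacPhase(-0.3, peaks)))
})

test_that("respiratory phase separates inhalation from exhalation", {
  t0 <- seq(0, 60, by = 0.02)
  belt <- sin(2 * pi * 0.3 * t0)
  phi <- respiratoryPhase(belt, rate = 50)
  expect_true(all(phi > -pi - 1e-9 & phi <= pi + 1e-9))
  ## within a rising half-breath the phase increases monotonically
  rising <- which(t0 > 0.1 & t0 < 0.7)   # first ascent of the sinusoid
  expect_true(all(diff(phi[rising]) >= 0))
  ## sign flips at the extrema (descending phase is negative)
  falling <- which(t0 > 1.0 & t0 < 1.5)
  expect_true(all(phi[falling] <= 0))
  ## rank-based: affine rescaling leaves the phase unchanged up to rank
  ## reshuffles among floating-point near-ties (~pi/N each) and sign
  ## flips of the derivative at isolated extrema
  phi2 <- respiratoryPhase(3 * belt + 7, rate = 50)
  expect_gt(mean(abs(phi2 - phi) < 0.02), 0.99)
  expect_error(respiratoryPhase(rep(2, 100), rate = 50), "constant")
})

test_that("phase Fourier expansion yields the RETROICOR block", {
  phi <- runif(150, 0, 2 * pi)
  M <- phaseFourierRegressors(phi, order = 5)
  expect_equal(ncol(M), 10)
  expect_true(all(M >= -1 & M <= 1))
  M0 <- phaseFourierRegressors(rep(0, 10), order = 5)
  expect_equal(unname(M0[, 1:5]), matrix(0, 10, 5))
  expect_equal(unname(M0[, 6:10]), matrix(1, 10, 5))
  ## near-orthogonality for uniform phase (Monte-Carlo Gram matrix)
  set.seed(8)
  big <- phaseFourierRegressors(runif(20000, 0, 2 * pi), order = 5)
  G <- crossprod(big) / nrow(big)
  offDiag <- G - diag(diag(G))
  expect_lt(max(abs(offDiag)), 0.05)
})

test_that("slow cardiorespiratory regressors track the generated rates", {
  cfg <- simulationConfig(seed = 17, heartRate = 60, respRate = 18)
  rec <- simulatePhysio(cfg)
  rec@cardiacPeaks <- detectCardiacPeaks(rec)
  S <- slowPhysioRegressors(rec, nVolumes = 150, tr = 2)
  expect_equal(colnames(S), c("hr_freq", "hrv", "belt_raw", "resp_freq",
                              "resp_amp", "rvt"))
  inner <- 5:145
  expect_true(all(abs(S[inner, "hr_freq"] - 1) < 0.1))
  expect_true(all(S[inner, "hrv"] < 0.1))
  ## respiration frequency near 0.3 Hz up to one zero-crossing quantum
  expect_true(all(abs(S[inner, "resp_freq"] - 0.3) < 0.3 / 7 + 0.05))
  expect_true(all(is.finite(S)))
})

test_that("RVT is linear in the breathing amplitude", {
  t0 <- seq(0, 300 - 0.02, by = 0.02)
  mk <- function(A) new("PhysioRecording",
                        pulse = 1 + sin(2 * pi * t0), resp = A *
                          sin(2 * pi * 0.3 * t0),
                        pulseRate = 50, respRate = 50,
                        cardiacPeaks = seq(0.25, 299, by = 1))
  S1 <- slowPhysioRegressors(mk(1), 150, 2)
  S2 <- slowPhysioRegressors(mk(2), 150, 2)
  inner <- 5:145
  expect_lt(sd(S1[inner, "rvt"]) / mean(S1[inner, "rvt"]), 0.1)
  expect_equal(S2[inner, "rvt"], 2 * S1[inner, "rvt"], tolerance = 1e-8)
})

test_that("nuisance assembly produces the 33-column labelled design", {
  sess <- simulateSession(simulationConfig(seed = 19))
  nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                            150, 2)
  expect_equal(ncol(designMatrix(nd)), 33)
  labs <- designLabels(nd)
  expect_equal(sum(startsWith(labs, "card_")), 10)
  expect_equal(sum(startsWith(labs, "resp_")) -
                 sum(labs %in% c("resp_freq", "resp_amp")), 10)
  expect_true(all(c("hr_freq", "hrv", "belt_raw", "resp_freq",
                    "resp_amp", "rvt", "ventricle") %in% labs))
  expect_false(anyDuplicated(labs) > 0)
  expect_equal(unname(colMeans(designMatrix(nd))), rep(0, 33),
               tolerance = 1e-10)

  ## RETROICOR block alone: 10 + 10 + 6 = 26 columns
  peaks <- detectCardiacPeaks(sess$physio)
  tMid <- (0:149) * 2 + 1
  cardiac <- phaseFourierRegressors(cardiacPhase(tMid, peaks), 5, "card")
  phiR <- respiratoryPhase(sess$physio)
  respIdx <- pmin(round(tMid * sess$physio@respRate) + 1, length(phiR))
  resp <- phaseFourierRegressors(phiR[respIdx], 5, "resp")
  recPk <- sess$physio; recPk@cardiacPeaks <- peaks
  slow <- slowPhysioRegressors(recPk, 150, 2)
  retro <- assembleNuisanceDesign(cardiac = cardiac, resp = resp,
                                  slow = slow)
  expect_equal(ncol(designMatrix(retro)), 26)

  ## omitting the ventricle leaves 32 columns without that label
  no4v <- assembleNuisanceDesign(motion = sess$motion, cardiac = cardiac,
                                 resp = resp, slow = slow)
  expect_equal(ncol(designMatrix(no4v)), 32)
  expect_false("ventricle" %in% designLabels(no4v))

  ## collinear blocks are rejected with the offending labels
  expect_error(assembleNuisanceDesign(motion = sess$motion,
                                      ventricle = sess$motion[, 1]),
               "collinear")
})

test_that("regressing the design removes injected physiological bleed", {
  cfg <- simulationConfig(seed = 23, couplingMode = "none", nRois = 1,
                          boldNoiseSd = 0.1, physioBleed = 1)
  sess <- simulateSession(cfg)
  y <- boldMatrix(sess$bold)[, 1]
  nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                            150, 2)
  resid <- stats::residuals(stats::lm.fit(
    cbind(1, designMatrix(nd)), y))
  ## aliased cardiac (1 Hz at fs 0.5 -> 0 Hz band edge) and respiratory
  ## (0.3 Hz -> 0.2 Hz) components: compare band power before and after
  P <- function(v, f0) {
    n <- length(v)
    sp <- Mod(fft(v - mean(v)))^2
    f <- (0:(n - 1)) * 0.5 / n
    sum(sp[abs(f - f0) < 0.02])
  }
  aliasResp <- abs(0.3 - 0.5)  # 0.2 Hz
  expect_lt(P(resid, aliasResp), 0.1 * P(y, aliasResp))
})
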