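test_that("cleaning removes nuisance structure and standardizes", {
  sess <- simulateSession(simulationConfig(seed = 33, couplingMode = "none",
                                           nRois = 1, boldNoiseSd = 0.05,
                                           physioBleed = 1))
  nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                            150, 2)
  ## a series that IS nuisance: residual variance nearly vanishes
  pureNuis <- designMatrix(nd) %*% rnorm(33)
  resid <- stats::residuals(stats::lm.fit(
    cbind(1, dctHighpassBasis(150, 2), designMatrix(nd)), pureNuis))
  expect_lt(var(resid), 0.05 * var(pureNuis))
  ## an embedded component orthogonal to the cleaning design survives
  set.seed(2)
  raw <- rnorm(150)
  embedded <- stats::residuals(stats::lm.fit(
    cbind(1, dctHighpassBasis(150, 2), designMatrix(nd)), raw))
  y <- drop(pureNuis) + embedded
  cl <- cleanSignal(y, nd, tr = 2)
  expect_gt(cor(cl, embedded), 0.95)
  expect_equal(mean(cl), 0, tolerance = 1e-8)
  expect_equal(sd(cl), 1, tolerance = 1e-8)
})

test_that("pseudo-event detection finds upward threshold crossings", {
  ev <- detectPseudoEvents(c(0, 0, 2, 2, 0, 0, 1.5, 0), k = 1)
  expect_equal(eventOnsets(ev), c(3L, 7L))   # 1-based volume indices
  expect_equal(nEvents(ev), 2)
  expect_error(detectPseudoEvents(rep(0.5, 20), k = 1),
               "no suprathreshold events")
  ## two-sided detection also catches negative excursions
  ev2 <- detectPseudoEvents(c(0, -2, 0, 2, 0), k = 1, twoSided = TRUE)
  expect_equal(eventOnsets(ev2), c(2L, 4L))
  ## event count is non-increasing in the threshold for unimodal
  ## excursions (isolated bumps of graded heights)
  bump <- dnorm(seq(-3, 3, length.out = 21)) / dnorm(0)
  z <- numeric(200)
  for (i in seq_along(heights <- c(0.6, 1.2, 1.8, 2.4)))
    z[(i * 40):(i * 40 + 20)] <- heights[i] * bump
  counts <- vapply(c(0.5, 1, 1.5, 2), function(k)
    tryCatch(nEvents(detectPseudoEvents(z, k)), error = function(e) 0L),
    integer(1))
  expect_equal(counts, c(4L, 3L, 2L, 1L))
})

test_that("detected onsets align with generated events", {
  ev <- simulateEventBold(300, 2, eventRate = 6, ttp = 5, noiseSd = 0.2,
                          seed = 12)
  cl <- cleanSignal(ev$y, NULL, tr = 2)
  det <- eventOnsets(detectPseudoEvents(cl, k = 1))
  ## detections lag the neural events by the kernel rise; count how many
  ## are within one volume of a true event after the typical 1-volume lag
  hits <- vapply(det, function(o)
    any(abs((o - 1) - ev$onsets) <= 1), logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("basis fits recover kernels generated from the basis itself", {
  ## y built from the canonical column of the fitted basis: TTP error is
  ## at most one fine-grid step, R2 = 1, doubling y doubles the betas
  basis <- hrfBasisSet(hrfParameters(dt = 0.1))
  kTr <- basis@canonical[seq(1, length(basis@canonical), by = 20)]
  set.seed(4)
  train <- as.numeric(runif(300) < 0.1)
  y <- pupilAAS:::.causalConv(train, kTr)
  est <- fitEventHrf(y, which(train > 0), basis, tr = 2, lagSearch = 0:4)
  fineArgmax <- (which.max(basis@canonical) - 1) * 0.1
  expect_equal(ttp(est), fineArgmax, tolerance = 0.1 + 1e-9)
  expect_gt(est@fitR2, 0.999)
  expect_equal(est@onsetShift, 0)
  est2 <- fitEventHrf(2 * y, which(train > 0), basis, tr = 2,
                      lagSearch = 0:4)
  expect_equal(est2@basisBetas, 2 * est@basisBetas, tolerance = 1e-8)
  expect_equal(ttp(est2), ttp(est))
})

test_that("fits recover generated double-gamma TTPs near the basis span", {
  for (p1 in c(5, 5.5, 6)) {
    ev <- simulateEventBold(300, 2, eventRate = 6, ttp = p1, noiseSd = 0,
                            seed = 40 + p1)
    est <- fitEventHrf(as.numeric(scale(ev$y)), ev$onsets, hrfBasisSet(),
                       tr = 2)
    truePeak <- denseKernelArgmax(p1, dt = 0.01)
    expect_lt(abs(ttp(est) - truePeak), 1)
  }
})

test_that("Wiener recovery inverts the convolution", {
  ev <- simulateEventBold(150, 2, eventRate = 8, ttp = 5, noiseSd = 0,
                          seed = 21)
  xTrue <- numeric(150); xTrue[ev$onsets] <- 1
  xhat <- wienerRecoverNeural(ev$y, ev$kernel, noiseFloor = 1e-10)
  expect_gt(cor(xhat, xTrue), 0.99)
  ## identity kernel returns the input
  y <- rnorm(64)
  expect_equal(wienerRecoverNeural(y, c(1, rep(0, 5)),
                                   noiseFloor = 1e-12), y,
               tolerance = 1e-6)
  expect_error(wienerRecoverNeural(y, c(1, 0), noiseFloor = 0),
               "positive")
  ## stronger regularization strictly reduces high-frequency power
  hf <- function(v) {
    P <- Mod(fft(v - mean(v)))^2
    n <- length(v)
    f <- (0:(n - 1)) / n
    sum(P[f > 0.3 & f < 0.7])
  }
  noisy <- ev$y + rnorm(150, sd = 0.3)
  x1 <- wienerRecoverNeural(noisy, ev$kernel, noiseFloor = 1e-4)
  x2 <- wienerRecoverNeural(noisy, ev$kernel, noiseFloor = 1e-1)
  expect_lt(hf(x2), hf(x1))
})

test_that("per-ROI estimation concatenates sessions with a seam guard", {
  ev1 <- simulateEventBold(150, 2, ttp = 5, noiseSd = 0.2, seed = 31)
  est1 <- estimateRoiHrf(list(ev1$y), NULL, tr = 2)
  expect_s4_class(est1, "HRFEstimate")
  ## identical sessions: the duplicated estimate stays close to the
  ## single-session one (seam guard drops boundary events)
  est2 <- estimateRoiHrf(list(ev1$y, ev1$y), NULL, tr = 2)
  expect_lt(abs(ttp(est2) - ttp(est1)), 1)
  ## session order does not matter
  ev2 <- simulateEventBold(150, 2, ttp = 5, noiseSd = 0.2, seed = 32)
  a <- estimateRoiHrf(list(ev1$y, ev2$y), NULL, tr = 2)
  b <- estimateRoiHrf(list(ev2$y, ev1$y), NULL, tr = 2)
  expect_lt(abs(ttp(a) - ttp(b)), 1)
})
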