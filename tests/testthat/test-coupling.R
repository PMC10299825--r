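test_that("the TTP sweep covers 6 kernels and 12 regressor conditions", {
  sess <- simulateSession(simulationConfig(seed = 43, couplingMode = "lag",
                                           nRois = 2))
  regS <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
  regD <- preprocessPupil(sess$pupil, "derivative", tr = 2,
                          nVolumes = 150)
  sw <- ttpSweep(list(sess$bold), list(regS), list(regD), NULL, tr = 2)
  expect_equal(sort(unique(sw$ttp)), 1:6)
  expect_equal(nrow(sw), 2 * 12)           # 2 ROIs x 6 TTPs x 2 variants
  expect_setequal(unique(sw$variant), c("size", "derivative"))
  expect_true(all(is.finite(sw$t)))
})

test_that("cross-correlation respects its sign convention", {
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.6), 150))
  self <- suppressWarnings(crossCorrelateLags(x, x, tr = 2))
  expect_equal(nrow(self), 9)
  expect_equal(self$r[self$lag_s == 0], 1)
  expect_true(all(self$r[self$lag_s == 0] >= self$r))
  expect_equal(self$z, atanh(pmin(self$r, 1 - 1e-12)), tolerance = 1e-6)
  expect_match(attr(self, "convention"), "pupil precedes")
  ## bold(t) = pupil(t - 4 s): pupil precedes, argmax at -4
  pupil <- as.numeric(arima.sim(list(ar = 0.8), 200))[1:154]
  bold <- pupil[1:150]
  pupilNow <- pupil[3:152]
  xc <- suppressWarnings(crossCorrelateLags(pupilNow, bold, tr = 2))
  expect_equal(xc$lag_s[which.max(xc$r)], -4)
  expect_error(crossCorrelateLags(rnorm(12), rnorm(12), tr = 2),
               "overlap")
})

test_that("null cross-correlations are centred on zero", {
  set.seed(10)
  B <- 1000
  acc <- matrix(0, B, 9)
  for (i in seq_len(B)) {
    acc[i, ] <- crossCorrelateLags(rnorm(150), rnorm(150), tr = 2)$r
  }
  expect_true(all(abs(colMeans(acc)) < 0.02))
})

test_that("partial correlation matches the analytic formula", {
  set.seed(12)
  ## confound independent of both: partialing changes nothing much
  dz <- replicate(200, {
    p <- rnorm(150); y <- 0.5 * p + rnorm(150); g <- rnorm(150)
    pc <- partialCorrelationLag0(p, y, g)
    abs(pc$zFull - pc$zPartial)
  })
  expect_lt(mean(dz), 0.05)
  ## target equal to the confound: partial correlation vanishes
  p <- rnorm(500); g <- 0.4 * p + rnorm(500)
  pc <- partialCorrelationLag0(p, g, g)
  expect_lt(abs(pc$rPartial), 1e-10)
  expect_error(partialCorrelationLag0(p, g, rep(1, 500)), "constant")
  ## shared-variance construction vs the closed-form partial correlation
  for (i in 1:20) {
    set.seed(100 + i)
    g <- rnorm(300)
    p <- rnorm(300)
    y <- 0.5 * g + 0.4 * p + rnorm(300, sd = 0.8)
    pc <- partialCorrelationLag0(p, y, g)
    expect_equal(pc$rPartial, partialCorOracle(p, y, g),
                 tolerance = 1e-8)
  }
})

test_that("cross-spectral density localizes shared oscillations", {
  t0 <- seq(0, 298, by = 2)
  x <- sin(2 * pi * 0.1 * t0)
  cs <- crossSpectralDensity(x, x, tr = 2)
  expect_lt(abs(attr(cs, "peakFrequency") - 0.1), 0.5 / 256 + 1e-9)
  expect_true(all(cs$frequency_hz <= 0.25 + 1e-12))
  ## one constant series: essentially no cross-power anywhere
  cZero <- crossSpectralDensity(x, rep(1, length(x)), tr = 2)
  expect_lt(max(cZero$cross_power), 1e-20)
  ## magnitude is symmetric under swapping the inputs
  set.seed(13)
  a <- rnorm(150); b <- rnorm(150)
  s1 <- crossSpectralDensity(a, b, tr = 2)
  s2 <- crossSpectralDensity(b, a, tr = 2)
  expect_equal(s1$cross_power, s2$cross_power, tolerance = 1e-12)
  expect_error(crossSpectralDensity(a[1:5], b[1:5], tr = 2, window = 10),
               "window")
})

test_that("the rectangular full-length cross-spectrum is the Fourier pair
           of the circular cross-covariance", {
  set.seed(14)
  x <- rnorm(32); y <- rnorm(32)
  cs <- crossSpectralDensity(x, y, tr = 2, window = 32, overlap = 0,
                             nfft = 32, taper = "rect")
  S <- attr(cs, "complexSpectrum")
  ## package scaling: S = Conj(X) Y / (n fs); invert and compare with the
  ## directly computed circular cross-covariance
  n <- 32; fs <- 0.5
  ccHat <- Re(fft(S, inverse = TRUE)) * fs / n
  ccOracle <- circularCrossCov(x, y)
  expect_lt(max(abs(ccHat - ccOracle)), 1e-8)
})

test_that("lag-0 synthetic data gives convergent sweep and lag results", {
  ## consistency of the two headline analyses on the same sessions
  tmat <- matrix(0, 6, 5); zmat <- matrix(0, 9, 5)
  for (i in 1:5) {
    sess <- simulateSession(simulationConfig(seed = 900 + i,
                                             couplingMode = "lag",
                                             couplingLag = 0, nRois = 1,
                                             boldNoiseSd = 0.5))
    reg <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
    nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                              150, 2)
    sw <- ttpSweep(list(sess$bold), list(reg), NULL, list(nd), tr = 2)
    tmat[, i] <- sw$t
    cl <- cleanSignal(boldMatrix(sess$bold)[, 1], nd, 2, ar1 = FALSE)
    zmat[, i] <- crossCorrelateLags(reg, cl, tr = 2)$z
  }
  expect_equal(which.max(rowMeans(tmat)), 1)        # shortest TTP wins
  expect_equal(which.max(rowMeans(zmat)), 5)        # lag 0 wins
})
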