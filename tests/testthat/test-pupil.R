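mkTrace <- function(diameter, valid = NULL, rate = 250) {
  pupilTrace(diameter = diameter, valid = valid, rate = rate)
}

test_that("blink interpolation widens by 100 ms before and 400 ms after", {
  rate <- 250
  n <- 3 * rate                       # 3 s trace
  t0 <- (seq_len(n) - 1) / rate
  valid <- !(t0 >= 1.0 & t0 <= 1.2)   # blink spanning 1.0-1.2 s
  tr <- mkTrace(sin(t0) + 5, valid)
  out <- interpolateBlinks(tr)
  expect_true(all(isValid(out)))
  ## replaced window is [0.9, 1.6]; a sample at 0.85 s and one at 1.65 s
  ## keep their original values, samples inside are on the connecting line
  orig <- pupilDiameter(tr)
  new <- pupilDiameter(out)
  expect_equal(new[t0 < 0.9 - 1e-9], orig[t0 < 0.9 - 1e-9])
  expect_equal(new[t0 > 1.6 + 1e-9], orig[t0 > 1.6 + 1e-9])
  expect_false(isTRUE(all.equal(new[t0 >= 1.0 & t0 <= 1.2],
                                orig[t0 >= 1.0 & t0 <= 1.2])))
  ## the raw invalid fraction is retained for QC
  expect_equal(out@rawInvalidFraction, mean(!valid))
})

test_that("interpolation is the identity on fully valid traces", {
  tr <- mkTrace(rnorm(1000) + 5)
  out <- interpolateBlinks(tr)
  expect_equal(pupilDiameter(out), pupilDiameter(tr))
})

test_that("interpolated values are linear between the flanking samples", {
  rate <- 10  # pre = 1 sample, post = 4 samples at 10 Hz
  diameter <- c(rep(4, 10), rep(0, 5), rep(6, 15))
  valid <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 15))
  out <- interpolateBlinks(mkTrace(diameter, valid, rate = rate))
  ## widened gap: samples 10..19; flanked by 4.0 (sample 9) and 6.0 (20)
  got <- pupilDiameter(out)[9:20]
  expect_equal(got, seq(4, 6, length.out = 12))
})

test_that("boundary blinks hold the nearest valid value", {
  diameter <- c(rep(0, 50), rep(5, 200))
  valid <- c(rep(FALSE, 50), rep(TRUE, 200))
  out <- interpolateBlinks(mkTrace(diameter, valid))
  expect_equal(pupilDiameter(out)[1], 5)
  expect_error(interpolateBlinks(mkTrace(rep(0, 100), rep(FALSE, 100))),
               "all samples invalid")
})

test_that("invalid-fraction QC applies the strict 25% rule", {
  n <- 1000
  ok <- qcInvalidFraction(mkTrace(rnorm(n), rep(TRUE, n)))
  expect_equal(ok$fraction, 0)
  expect_true(ok$include)
  ex <- qcInvalidFraction(mkTrace(rnorm(n), rep(c(FALSE, TRUE),
                                                c(300, 700))))
  expect_equal(ex$fraction, 0.3)
  expect_false(ex$include)
  boundary <- qcInvalidFraction(mkTrace(rnorm(n), rep(c(FALSE, TRUE),
                                                      c(250, 750))))
  expect_equal(boundary$fraction, 0.25)
  expect_true(boundary$include)   # strict inequality
})

test_that("derivative matches analytic slopes", {
  expect_equal(pupilDiameter(computeDerivative(mkTrace(rep(3, 100)))),
               rep(0, 100))
  t0 <- (0:999) / 250
  ramp <- computeDerivative(mkTrace(5 + 0.5 * t0))
  expect_equal(pupilDiameter(ramp), rep(0.5, 1000), tolerance = 1e-8)
  ## sine at 0.1 Hz: derivative amplitude 2*pi*0.1*A
  tS <- (0:249999) / 250
  A <- 2
  d <- pupilDiameter(computeDerivative(mkTrace(A * sin(2 * pi * 0.1 * tS))))
  expect_equal(max(d[100:200000]), 2 * pi * 0.1 * A, tolerance = 1e-3)
})

test_that("backward shift moves features earlier and records provenance", {
  imp <- rep(0, 5000); imp[2501] <- 1        # impulse at t = 10 s
  tr <- mkTrace(imp)
  expect_equal(pupilDiameter(shiftTrace(tr, 0)), imp)
  shifted <- shiftTrace(tr, 1)
  expect_equal(which(pupilDiameter(shifted) == 1), 2251)  # t = 9 s
  expect_error(shiftTrace(tr, 30), "exceeds")
  expect_error(shiftTrace(tr, 0.0013), "multiple")
  ## cross-correlating shifted against unshifted peaks at the shift
  sim <- simulatePupil(simulationConfig(seed = 31, blinkRate = 0))
  reg0 <- preprocessPupil(sim$trace, "size", shift = 0, tr = 2,
                          nVolumes = 150)
  reg2 <- preprocessPupil(sim$trace, "size", shift = 2, tr = 2,
                          nVolumes = 150)
  ## reg2 anticipates reg0 by 2 s: with the backward-shifted series in
  ## the BOLD slot, the unshifted pupil follows it at lag +2
  xc <- crossCorrelateLags(reg0, regressorValues(reg2), tr = 2)
  expect_equal(xc$lag_s[which.max(xc$r)], 2)
})

test_that("TR resampling drops per-bin outliers and keeps the length", {
  sim <- simulatePupil(simulationConfig(seed = 41))
  reg <- preprocessPupil(sim$trace, "size", tr = 2, nVolumes = 150)
  expect_equal(nVolumes(reg), 150)

  tr <- mkTrace(rep(7, 1000))
  out <- resampleToVolumes(tr, tr = 2, nVolumes = 2)
  expect_equal(regressorValues(out), c(7, 7))
  expect_equal(out@recomputedFraction, 0)

  ## bin with one gross outlier: recomputed mean equals the inlier mean
  set.seed(1)
  inliers <- rnorm(499, mean = 5, sd = 0.1)
  bin <- c(inliers, 50)
  tr2 <- mkTrace(c(bin, rnorm(500, 5, 0.1)))
  out2 <- resampleToVolumes(tr2, tr = 2, nVolumes = 2)
  expect_equal(regressorValues(out2)[1], mean(inliers), tolerance = 1e-10)
  expect_equal(out2@recomputedFraction, 1 / 1000)

  expect_error(resampleToVolumes(tr2, tr = 2, nVolumes = 3), "too short")
})

test_that("raising the outlier threshold never drops more samples", {
  sim <- simulatePupil(simulationConfig(seed = 51, blinkRate = 30))
  trI <- interpolateBlinks(sim$trace)
  fractions <- vapply(c(1, 2, 3, 4), function(k)
    resampleToVolumes(trI, 2, 150, outlierK = k)@recomputedFraction,
    numeric(1))
  expect_true(all(diff(fractions) <= 0))
})

test_that("the pipeline runs in the fixed order and is length-stable", {
  sim <- simulatePupil(simulationConfig(seed = 61, blinkRate = 25))
  for (variant in c("size", "derivative")) {
    reg <- preprocessPupil(sim$trace, variant, tr = 2, nVolumes = 150)
    expect_equal(nVolumes(reg), 150)
    expect_equal(regressorVariant(reg), variant)
    expect_equal(reg@shiftApplied, 1)
  }
})
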