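test_that("DCT drift basis has the closed-form count and orthogonality", {
  B <- dctHighpassBasis(150, 2, 128)
  expect_equal(ncol(B), 4)                      # floor(600/128)
  G <- crossprod(B)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  expect_error(dctHighpassBasis(150, 2, cutoff = 3), "cutoff")
  ## projecting out the basis annihilates a constant-plus-very-slow
  ## (period 600 s) trend; cosine phase aligns with the DCT columns
  t0 <- 0:149
  X <- cbind(1, B)
  trend <- 1 + cos(2 * pi * t0 / 300)
  resid <- stats::residuals(stats::lm.fit(X, trend))
  dm <- trend - mean(trend)
  expect_lt(sqrt(mean(resid^2)), 0.05 * sqrt(mean(dm^2)))
  ## worst case (odd phase at the window edge), frozen from the
  ## projection oracle: ~10.5% RMS residual
  trendS <- 1 + sin(2 * pi * t0 / 300)
  residS <- stats::residuals(stats::lm.fit(X, trendS))
  ratio <- sqrt(mean(residS^2)) /
    sqrt(mean((trendS - mean(trendS))^2))
  expect_equal(ratio, 0.1050915, tolerance = 1e-5)
})

test_that("prewhitened GLM betas match the normal-equations oracle", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- 2 * x + Z %*% c(0.5, -1, 0.2) + rnorm(n, sd = 1e-4)
  X <- cbind(pupil = x, Z)
  fit <- fitAr1Glm(y, X, target = "pupil")
  ## oracle: solve the prewhitened normal equations directly
  rho <- arRho(fit)
  W <- diag(n); W[1, 1] <- sqrt(1 - rho^2)
  for (i in 2:n) W[i, i - 1] <- -rho
  Xf <- cbind(X, intercept = 1)
  betaOracle <- solve(t(W %*% Xf) %*% (W %*% Xf),
                      t(W %*% Xf) %*% (W %*% y))
  expect_equal(unname(fit@betas), unname(drop(betaOracle)),
               tolerance = 1e-6)
  expect_equal(fit@betas[["pupil"]], 2, tolerance = 1e-3)
  expect_gt(tStatistic(fit), 100)
})

test_that("orthogonal nuisance columns leave the target beta unchanged", {
  set.seed(6)
  n <- 200
  x <- rnorm(n); x <- x - mean(x)
  ## build nuisance orthogonal to x and the intercept
  Zr <- matrix(rnorm(n * 4), n, 4)
  Zo <- stats::residuals(stats::lm.fit(cbind(1, x), Zr))
  y <- 1.5 * x + rnorm(n)
  b1 <- fitAr1Glm(y, cbind(pupil = x), target = "pupil")
  b2 <- fitAr1Glm(y, cbind(pupil = x, Zo), target = "pupil")
  ## same OLS beta; the AR(1) step re-estimates rho, so compare the
  ## unwhitened projections via a shared rho = 0 refit
  ols1 <- qr.solve(cbind(x, 1), y)[1]
  ols2 <- qr.solve(cbind(x, Zo, 1), y)[1]
  expect_equal(ols1, ols2, tolerance = 1e-8)
  expect_equal(b1@betas[["pupil"]], b2@betas[["pupil"]], tolerance = 1e-3)
})

test_that("prewhitening with rho = 0 is the identity (OLS recovered)", {
  set.seed(7)
  M <- matrix(rnorm(60), 20, 3)
  expect_identical(pupilAAS:::.prewhiten(M, 0), M)
  ## t invariance to affine rescaling of regressor and response
  n <- 100
  x <- rnorm(n)
  y <- x + rnorm(n)
  f1 <- fitAr1Glm(y, cbind(pupil = x), target = "pupil")
  f2 <- fitAr1Glm(10 * y + 3, cbind(pupil = 0.2 * x), target = "pupil")
  expect_equal(tStatistic(f1), tStatistic(f2), tolerance = 1e-10)
})

test_that("the first-level t is calibrated on white-noise nulls", {
  set.seed(11)
  n <- 150
  x <- regressorValues(convolveAtTr(
    new("PupilRegressor", values = rnorm(n), tr = 2),
    doubleGammaHrf(hrfParameters(p1 = 2, dt = 2))))
  B <- 1500
  hits <- 0
  means <- numeric(B)
  for (i in seq_len(B)) {
    y <- rnorm(n)
    fit <- fitAr1Glm(y, cbind(pupil = x), target = "pupil")
    means[i] <- tStatistic(fit)
    if (2 * stats::pt(-abs(tStatistic(fit)), fit@dof) < 0.05)
      hits <- hits + 1
  }
  expect_lt(abs(mean(means)), 0.1)
  expect_lt(abs(hits / B - 0.05), 0.015)
})

test_that("two identical sessions give the single-session statistic", {
  sess <- simulateSession(simulationConfig(seed = 29, couplingMode = "lag",
                                           nRois = 1, boldNoiseSd = 0.5))
  reg <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
  nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                            150, 2)
  y <- boldMatrix(sess$bold)[, 1]
  one <- pupilCouplingTstat(list(y), list(reg), list(nd), tr = 2)
  two <- pupilCouplingTstat(list(y, y), list(reg, reg), list(nd, nd),
                            tr = 2)
  expect_equal(two@betaTarget, one@betaTarget, tolerance = 1e-6)
  ## and the duplicated-data t is larger purely through the doubled dof
  expect_gt(abs(tStatistic(two)), abs(tStatistic(one)))
})

test_that("coupled synthetic data yields strongly positive coupling t", {
  tvals <- vapply(1:5, function(i) {
    sess <- simulateSession(simulationConfig(seed = 500 + i,
                                             couplingMode = "lag",
                                             couplingLag = 0,
                                             couplingGain = 1,
                                             boldNoiseSd = 0.5,
                                             nRois = 1))
    reg <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
    nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                              150, 2)
    k <- doubleGammaHrf(hrfParameters(p1 = 1, dt = 2))
    tStatistic(pupilCouplingTstat(list(boldMatrix(sess$bold)[, 1]),
                                  list(convolveAtTr(reg, k)), list(nd),
                                  tr = 2))
  }, numeric(1))
  ## p < 0.001 one-sided at ~110 dof corresponds to t > 3.2
  expect_true(all(tvals > 3.2))
})
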