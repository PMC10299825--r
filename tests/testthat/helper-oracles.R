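## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths.

## brute-force Benjamini-Hochberg step-up: adjusted p_i = min over j with
## p_(j) >= p_(i) of m * p_(j) / j, capped at 1
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## closed-form partial correlation of x and y given z from the covariance
partialCorOracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

## circular cross-covariance sum_i x_i y_{i+l} / n (both demeaned)
circularCrossCov <- function(x, y) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  vapply(0:(n - 1), function(l) {
    idx <- ((seq_len(n) - 1 + l) %% n) + 1
    sum(x * y[idx]) / n
  }, numeric(1))
}

## closed-form double-gamma difference evaluated densely (the reference for
## kernel argmax values)
denseKernelArgmax <- function(p1, p2 = 16, p3 = 1, p4 = 1, p5 = 6,
                              p7 = 32, dt = 0.01) {
  t0 <- seq(0, p7, by = dt)
  h <- dgamma(t0, shape = p1 / p3, scale = p3) -
    dgamma(t0, shape = p2 / p4, scale = p4) / p5
  t0[which.max(h)]
}

## periodogram band mass via base fft (no taper), excluding DC
bandMass <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- f > 0 & f <= fs / 2
  inb <- keep & f >= lo & f <= hi
  sum(P[inb]) / sum(P[keep])
}

## quick session-level analysis used by several tests: pupil-size regressor,
## full nuisance design, cleaned single-ROI BOLD
prepSession <- function(sess, tr = 2, nVolumes = 150, shift = 1) {
  reg <- preprocessPupil(sess$pupil, "size", shift = shift, tr = tr,
                         nVolumes = nVolumes)
  nd <- buildNuisanceDesign(sess$physio, sess$motion, sess$ventricle,
                            nVolumes, tr)
  clean <- cleanSignal(boldMatrix(sess$bold)[, 1], nd, tr)
  list(reg = reg, nuisance = nd, clean = clean)
}
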