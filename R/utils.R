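## internal numeric helpers shared across modules

.demean <- function(x) x - mean(x)

.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant series")
  (x - mean(x)) / s
}

## causal discrete convolution truncated to length(x); zero history before
## the first sample
.causalConv <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

## derive independent sub-seeds from a master seed without disturbing the
## caller's RNG stream more than once
.deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

## lag-1 autocorrelation (Yule-Walker estimate)
.ar1Rho <- function(e) {
  denom <- sum(e^2)
  if (denom == 0) return(0)
  sum(e[-1] * e[-length(e)]) / denom
}

## Prais-Winsten prewhitening by the (1, -rho) filter within one block;
## the first observation is scaled by sqrt(1 - rho^2)
.prewhiten <- function(m, rho) {
  m <- as.matrix(m)
  n <- nrow(m)
  out <- m
  if (n >= 2L)
    out[-1L, ] <- m[-1L, , drop = FALSE] - rho * m[-n, , drop = FALSE]
  out[1L, ] <- sqrt(1 - rho^2) * m[1L, , drop = FALSE]
  out
}

.stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values")
  invisible(TRUE)
}
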