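#' @include AllClasses.R utils.R
NULL

#' Discrete-cosine high-pass drift basis
#'
#' DCT columns with periods longer than the cut-off, as used for slow
#' drift removal: \code{floor(2 * n * tr / cutoff)} columns, the k-th
#' being \code{cos(pi * (2t + 1) * k / (2n))}.  The columns are mutually
#' orthogonal and live on the nuisance side of every design.
#'
#' @param nVolumes number of volumes (at least 4).
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cut-off period in seconds (default 128, i.e.
#'   1/128 Hz).
#' @return A volumes x K matrix with labels \code{dct_1..K} (possibly zero
#'   columns when the run is shorter than half the cut-off).
#' @examples
#' ncol(dctHighpassBasis(150, 2))  # floor(600/128) = 4
#' @export
dctHighpassBasis <- function(nVolumes, tr, cutoff = 128) {
  if (nVolumes < 4) stop("need at least 4 volumes")
  if (cutoff <= 2 * tr)
    stop("cutoff must exceed twice the repetition time")
  K <- floor(2 * nVolumes * tr / cutoff)
  t0 <- 0:(nVolumes - 1)
  out <- sapply(seq_len(K),
                function(k) cos(pi * (2 * t0 + 1) * k / (2 * nVolumes)))
  out <- matrix(out, nrow = nVolumes)
  colnames(out) <- if (K > 0) paste0("dct_", seq_len(K)) else character()
  out
}

## core prewhitened least squares; X must include any intercept wanted.
## blocks: list of index vectors (sessions); rho estimated on pooled OLS
## residuals excluding cross-block lag pairs, prewhitening applied within
## blocks.
.ar1Fit <- function(y, X, blocks = list(seq_along(y))) {
  X <- as.matrix(X)
  n <- length(y)
  .stopIfNotFinite(y, "response")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix")
  e <- stats::residuals(stats::lm.fit(X, y))
  num <- 0; den <- sum(e^2)
  for (b in blocks) {
    eb <- e[b]
    num <- num + sum(eb[-1] * eb[-length(eb)])
  }
  rho <- if (den > 0) num / den else 0
  ## correct for the lag-1 autocorrelation the regression projection
  ## itself induces in the residuals (expected value under white noise:
  ## -sum_t H[t, t-1] / (n - rank), H the hat matrix); without this the
  ## many smooth nuisance columns bias rho negative and prewhitening
  ## inflates the t statistics of smooth regressors
  Q <- qr.Q(qrX)
  hOff <- 0
  for (b in blocks) {
    Qb <- Q[b, , drop = FALSE]
    hOff <- hOff + sum(Qb[-1, , drop = FALSE] * Qb[-nrow(Qb), ,
                                                   drop = FALSE])
  }
  rho <- rho + hOff / (n - qrX$rank)
  if (abs(rho) >= 0.99) {
    warning(sprintf("AR(1) estimate %.3f clamped to +/-0.99", rho))
    rho <- sign(rho) * 0.99
  }
  yw <- y; Xw <- X
  for (b in blocks) {
    yw[b] <- .prewhiten(matrix(y[b]), rho)
    Xw[b, ] <- .prewhiten(X[b, , drop = FALSE], rho)
  }
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  res <- fit$residuals
  dof <- n - qrX$rank
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(qr.R(qr(Xw)))
  list(beta = beta, rho = rho, dof = dof, sigma2 = sigma2,
       XtXinv = XtXinv)
}

#' First-level GLM with AR(1) prewhitening
#'
#' Ordinary least squares, Yule-Walker estimation of the residual lag-1
#' autocorrelation, Prais-Winsten prewhitening of response and design by
#' the \code{(1, -rho)} filter, and a refit.  The t statistic of the
#' target contrast (by default the unweighted mean of the target columns)
#' is returned with \code{n - rank(X)} degrees of freedom.
#'
#' @param y numeric response series.
#' @param X design matrix with unique column names.  An intercept column
#'   is appended automatically unless \code{addIntercept = FALSE}.
#' @param target label(s) of the column(s) of interest.
#' @param contrast optional numeric contrast over all design columns
#'   (after intercept addition); overrides \code{target} averaging.
#' @param blocks optional list of index vectors defining session blocks;
#'   prewhitening respects block boundaries.
#' @param addIntercept append a constant column (default \code{TRUE}).
#' @return A \linkS4class{GLMFit}.
#' @examples
#' x <- rnorm(100)
#' y <- 2 * x + rnorm(100, sd = 0.1)
#' fit <- fitAr1Glm(y, cbind(pupil = x), target = "pupil")
#' tStatistic(fit)
#' @export
fitAr1Glm <- function(y, X, target, contrast = NULL,
                      blocks = list(seq_along(y)), addIntercept = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (addIntercept) {
    if (length(blocks) > 1L) {
      ic <- matrix(0, length(y), length(blocks))
      for (j in seq_along(blocks)) ic[blocks[[j]], j] <- 1
      colnames(ic) <- paste0("intercept_s", seq_along(blocks))
    } else {
      ic <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
    }
    X <- cbind(X, ic)
  }
  if (!all(target %in% colnames(X)))
    stop("target column(s) not found in the design: ",
         paste(setdiff(target, colnames(X)), collapse = ", "))
  core <- .ar1Fit(y, X, blocks)
  if (is.null(contrast)) {
    contrast <- rep(0, ncol(X))
    contrast[match(target, colnames(X))] <- 1 / length(target)
  }
  cb <- sum(contrast * core$beta)
  se <- sqrt(core$sigma2 *
               drop(t(contrast) %*% core$XtXinv %*% contrast))
  betas <- core$beta
  names(betas) <- colnames(X)
  new("GLMFit", betas = betas, residVar = core$sigma2, dof = core$dof,
      tTarget = cb / se, betaTarget = cb, seTarget = se,
      ar1Rho = core$rho, targetLabel = target)
}

#' Pupil-BOLD coupling t statistic for one participant and ROI
#'
#' Assembles the first-level design block-diagonally over sessions: one
#' intercept, one DCT drift block and one copy of the nuisance design per
#' session, plus one (demeaned) pupil regressor column per session.  The
#' reported statistic tests the unweighted mean of the session pupil
#' betas.  Single-session participants use a one-block design.  Pupil
#' regressors are not orthogonalized against the nuisance columns.
#'
#' @param boldSessions list of numeric ROI series, one per session.
#' @param pupilSessions list of \linkS4class{PupilRegressor} (or numeric)
#'   aligned with \code{boldSessions}.
#' @param nuisanceSessions list of \linkS4class{NuisanceDesign} (or
#'   matrices), or \code{NULL} for no nuisance block.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cut-off period in seconds.
#' @return A \linkS4class{GLMFit} whose \code{tTarget} is the coupling t.
#' @examples
#' sess <- simulateSession(simulationConfig(seed = 6, boldNoiseSd = 0.2))
#' reg <- preprocessPupil(sess$pupil, "size", tr = 2, nVolumes = 150)
#' fit <- pupilCouplingTstat(list(boldMatrix(sess$bold)[, 1]), list(reg),
#'                           NULL, tr = 2)
#' tStatistic(fit)
#' @export
pupilCouplingTstat <- function(boldSessions, pupilSessions,
                               nuisanceSessions = NULL, tr,
                               cutoff = 128) {
  nSess <- length(boldSessions)
  stopifnot(nSess >= 1L, length(pupilSessions) == nSess)
  getVals <- function(p) if (is(p, "PupilRegressor")) p@values else
    as.numeric(p)
  getNuis <- function(nd) if (is(nd, "NuisanceDesign")) nd@design else
    as.matrix(nd)
  y <- numeric(0)
  blocks <- list()
  Xparts <- list()
  pupilLabels <- character(nSess)
  offset <- 0L
  for (s in seq_len(nSess)) {
    ys <- as.numeric(boldSessions[[s]])
    ns <- length(ys)
    pup <- .demean(getVals(pupilSessions[[s]]))
    if (length(pup) != ns)
      stop(sprintf("session %d: pupil regressor length %d != %d volumes",
                   s, length(pup), ns))
    drift <- dctHighpassBasis(ns, tr, cutoff)
    nuis <- if (!is.null(nuisanceSessions))
      getNuis(nuisanceSessions[[s]]) else NULL
    if (!is.null(nuis) && nrow(nuis) != ns)
      stop(sprintf("session %d: nuisance rows %d != %d volumes",
                   s, nrow(nuis), ns))
    cols <- cbind(pupil = pup, drift, nuis)
    colnames(cols) <- paste0("s", s, "_", colnames(cols))
    pupilLabels[s] <- paste0("s", s, "_pupil")
    Xparts[[s]] <- cols
    y <- c(y, ys)
    blocks[[s]] <- offset + seq_len(ns)
    offset <- offset + ns
  }
  ## block-diagonal assembly
  p <- vapply(Xparts, ncol, integer(1))
  X <- matrix(0, length(y), sum(p))
  labs <- character(sum(p))
  at <- 0L
  for (s in seq_len(nSess)) {
    X[blocks[[s]], at + seq_len(p[s])] <- Xparts[[s]]
    labs[at + seq_len(p[s])] <- colnames(Xparts[[s]])
    at <- at + p[s]
  }
  colnames(X) <- labs
  fitAr1Glm(y, X, target = pupilLabels, blocks = blocks,
            addIntercept = TRUE)
}
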