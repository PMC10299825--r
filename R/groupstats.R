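#' @include AllClasses.R utils.R
NULL

#' Fisher r-to-Z transform
#'
#' \code{z = atanh(r)}; coefficients at or beyond |r| = 1 are clamped to
#' \code{+/-(1 - 1e-12)} with a warning.
#'
#' @param r numeric correlation coefficient(s).
#' @return Numeric z value(s).
#' @examples
#' fisherZ(c(0, 0.5, -0.5))
#' @export
fisherZ <- function(r) {
  r <- as.numeric(r)
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clamped before the Fisher transform")
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(r)
}

#' One-sample t test against zero
#'
#' Second-level random-effects test over per-participant statistics.
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @return A list: \code{t}, \code{p} (two-sided), \code{dof},
#'   \code{mean}.
#' @examples
#' oneSampleTTest(c(2, 3, 4))
#' @export
oneSampleTTest <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (stats::sd(values) == 0) stop("zero variance: t undefined")
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
       dof = unname(ht$parameter), mean = unname(ht$estimate))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1.
#'
#' @param pvals numeric p values in [0, 1].
#' @return Adjusted p values (empty input gives empty output).
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
fdrAdjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "fdr")
}

#' Repeated-measures main effect across conditions
#'
#' One-way repeated-measures ANOVA with participant as the blocking
#' factor, testing whether the condition means differ (e.g. coupling
#' strength across the six TTP levels).  F has \code{(levels - 1,
#' (levels - 1) * (n - 1))} degrees of freedom.  A matrix whose
#' condition effect is exactly zero returns F = 0, p = 1 ("no effect").
#'
#' @param mat numeric matrix, participants x levels, complete (no
#'   missing cells).
#' @return A list: \code{F}, \code{p}, \code{dof} (length 2).
#' @examples
#' m <- matrix(rnorm(60), 10, 6)
#' rmAnovaMainEffect(m)
#' @export
rmAnovaMainEffect <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not supported")
  n <- nrow(mat); L <- ncol(mat)
  if (L < 2L || n < 2L) stop("need >= 2 levels and >= 2 participants")
  df <- data.frame(value = as.vector(mat),
                   level = factor(rep(seq_len(L), each = n)),
                   participant = factor(rep(seq_len(n), L)))
  fit <- stats::aov(value ~ level + Error(participant), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rownames(tab) <- trimws(rownames(tab))
  Fval <- tab["level", "F value"]
  pval <- tab["level", "Pr(>F)"]
  ## an exactly null condition effect leaves only floating-point dust in
  ## both sums of squares; report "no effect" instead of a 0/0 ratio
  ssLevel <- tab["level", "Sum Sq"]
  if (!is.finite(Fval) || ssLevel < 1e-12 * max(stats::var(df$value), 1)) {
    Fval <- 0; pval <- 1
  }
  list(F = unname(Fval), p = unname(pval),
       dof = c(L - 1, (L - 1) * (n - 1)))
}

#' Paired comparison of full and partial coupling
#'
#' Paired two-sided t test on Fisher-z correlation values, one pair per
#' participant, optionally FDR-corrected across ROIs by the caller.
#'
#' @param fullZ,partialZ paired numeric vectors of Fisher-z values.
#' @return A list: \code{t}, \code{p}, \code{dof}, \code{meanDiff}.
#' @examples
#' pairedComparison(rnorm(20, 0.4, 0.1), rnorm(20, 0.3, 0.1))
#' @export
pairedComparison <- function(fullZ, partialZ) {
  fullZ <- as.numeric(fullZ); partialZ <- as.numeric(partialZ)
  if (length(fullZ) != length(partialZ))
    stop("paired vectors must have equal length")
  d <- fullZ - partialZ
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, dof = length(d) - 1,
                                 meanDiff = 0))
    stop("zero variance of the paired differences")
  }
  ht <- stats::t.test(fullZ, partialZ, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       dof = unname(ht$parameter), meanDiff = unname(ht$estimate))
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling, for
#' individual-difference checks (mask size, tSNR, session stability).
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return A list: \code{rho}, \code{p}, \code{n}.
#' @examples
#' spearmanCorrelation(1:4, c(2, 1, 4, 3))
#' @export
spearmanCorrelation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least three pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Group table over conditions
#'
#' Applies the one-sample t test to each condition's per-participant
#' values and FDR-corrects within the chosen family.
#'
#' @param valueTable data.frame with columns \code{participant},
#'   \code{condition}, \code{value} (e.g. per-participant t or z).
#' @param familyBy how to define the FDR family: \code{"all"} corrects
#'   over every condition jointly; a column name present in
#'   \code{valueTable} (e.g. \code{"roi"}) corrects within its levels.
#' @return A data.frame with one row per condition: \code{n},
#'   \code{mean}, \code{t}, \code{p}, \code{p_fdr}.
#' @examples
#' tb <- data.frame(participant = rep(1:10, 2),
#'                  condition = rep(c("a", "b"), each = 10),
#'                  value = rnorm(20, 0.3))
#' groupConditionTable(tb)
#' @export
groupConditionTable <- function(valueTable, familyBy = "all") {
  stopifnot(all(c("participant", "condition", "value") %in%
                  names(valueTable)))
  conds <- unique(valueTable$condition)
  rows <- lapply(conds, function(cc) {
    v <- valueTable$value[valueTable$condition == cc]
    v <- v[is.finite(v)]
    tt <- oneSampleTTest(v)
    extra <- valueTable[valueTable$condition == cc, , drop = FALSE][1, ]
    data.frame(condition = cc, n = length(v), mean = mean(v), t = tt$t,
               p = tt$p,
               family = if (familyBy != "all" &&
                            familyBy %in% names(valueTable))
                 as.character(extra[[familyBy]]) else "all")
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$p_fdr[idx] <- fdrAdjust(out$p[idx])
  }
  out$family <- NULL
  out
}
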