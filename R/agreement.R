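#' Pearson correlation of paired observer scores
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom.  A constant score vector makes
#' the correlation undefined; the result is then \code{NA} with a reason.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return List with \code{r} and \code{p} (or \code{NA} + \code{reason}).
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    return(undefinedStat(c("r", "p"), "constant score vector"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation of paired observer scores
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with the
#' two-sided p-value from the same t approximation as
#' \code{\link{pearsonCor}}.  Perfectly monotone data give rho = +/-1 and
#' p = 0.
#'
#' @inheritParams pearsonCor
#' @return List with \code{rho} and \code{p} (or \code{NA} + \code{reason}).
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(undefinedStat(c("rho", "p"), "constant score vector"))
  n <- length(x)
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2))
}

#' Single-measure absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way ANOVA decomposition of a complete subjects x raters matrix into
#' between-subject (MSR), between-rater (MSC) and residual (MSE) mean
#' squares, combined as
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' for n subjects and k raters.  Negative values are legitimate and arise
#' when disagreement between raters exceeds the spread between subjects.
#'
#' @param scores numeric matrix, subjects in rows, raters in columns
#'   (complete, >= 3 subjects, >= 2 raters).
#' @return List with \code{icc} (or \code{NA} + \code{reason} when the
#'   matrix has no variance at all).
#' @examples
#' iccAbsoluteSingle(cbind(a = c(1, 2, 3), b = c(2, 3, 4)))$icc  # 2/3
#' @export
iccAbsoluteSingle <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  stopifnot(n >= 3L, k >= 2L, !anyNA(scores))
  grand <- mean(scores)
  rowM <- rowMeans(scores); colM <- colMeans(scores)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((scores - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0)
    return(undefinedStat("icc", "zero total variance"))
  list(icc = (msr - mse) / denom)
}

#' Bland-Altman limits of agreement
#'
#' Differences d = x - y summarized by their mean, sample standard
#' deviation, and the 95 percent limits of agreement mean +/- 1.96 SD; the
#' per-case (mean, difference) pairs are returned for plotting.
#'
#' @inheritParams pearsonCor
#' @return List with \code{mean_diff}, \code{sd_diff}, \code{loa_lower},
#'   \code{loa_upper} and a data frame \code{pairs} of per-case means and
#'   differences.
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       pairs = data.frame(mean = (x + y) / 2, diff = d))
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA F test on absolute deviations from each group's centre;
#' the mean centre is the classical Levene statistic, the median centre is
#' the Brown-Forsythe variant.  Degenerate input (all deviations zero)
#' returns \code{NA} with a reason.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each of length >= 2).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return List with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
leveneVariance <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 2L))
  ctr <- if (center == "mean") mean else stats::median
  dev <- lapply(groups, function(g) abs(g - ctr(g)))
  z <- unlist(dev)
  if (all(z == z[1L]))
    return(undefinedStat(c("F", "p"), "no variability in absolute deviations"))
  g <- factor(rep(seq_along(dev), lengths(dev)))
  N <- length(z); k <- nlevels(g)
  zbar <- mean(z); gm <- tapply(z, g, mean)
  ssb <- sum(lengths(dev) * (gm - zbar)^2)
  ssw <- sum((z - gm[g])^2)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = unname(Fstat), p = pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k)
}

#' Full agreement block for one observer pair
#'
#' Computes every continuous-score and categorical agreement statistic the
#' framework reports for a pair of observers: Pearson and Spearman
#' correlations of their disease-probability scores (both are always
#' reported), ICC(A,1), tie-aware Cohen's kappa of their credit vectors,
#' Bland-Altman limits of agreement, and Levene's test comparing the two
#' probability distributions.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param raterA,raterB rater identifiers.
#' @param tieTolerance,digits tie handling for the kappa component, as in
#'   \code{\link{assignCredit}}.
#' @param leveneCenter centre for \code{\link{leveneVariance}}.
#' @return Nested list with components \code{pearson}, \code{spearman},
#'   \code{icc}, \code{kappa}, \code{bland_altman}, \code{levene}.
#' @export
pairwiseAgreement <- function(x, raterA, raterB, tieTolerance = 1e-9,
                              digits = NULL, leveneCenter = "mean") {
  sa <- adScores(x, raterA); sb <- adScores(x, raterB)
  ba <- blandAltman(sa, sb)
  list(pearson = pearsonCor(sa, sb),
       spearman = spearmanCor(sa, sb),
       icc = iccAbsoluteSingle(cbind(sa, sb)),
       kappa = tieAwareKappa(creditMatrix(x, raterA, tieTolerance, digits),
                             creditMatrix(x, raterB, tieTolerance, digits)),
       bland_altman = ba[c("mean_diff", "sd_diff", "loa_lower", "loa_upper")],
       levene = leveneVariance(list(sa, sb), center = leveneCenter))
}
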