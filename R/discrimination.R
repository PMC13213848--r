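#' Empirical ROC curve of continuous disease-probability scores
#'
#' Sweeps the classifier "positive iff score >= t" over all unique score
#' values (plus sentinels), producing the staircase of (false positive
#' rate, true positive rate) points from (0,0) to (1,1).  Tied scores
#' across classes appear as diagonal segments.
#'
#' @param scores numeric vector of scores (higher = more disease-like).
#' @param labels logical or 0/1 vector, \code{TRUE}/1 = positive class.
#' @return Data frame with columns \code{threshold}, \code{fpr}, \code{tpr};
#'   both rates are non-decreasing along the curve.
#' @export
rocPoints <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1L))
  keep <- !duplicated(cbind(fpr, tpr))
  data.frame(threshold = thr[keep], fpr = fpr[keep], tpr = tpr[keep])
}

#' Area under the ROC curve, Mann-Whitney form
#'
#' The probability that a random positive case scores above a random
#' negative case, with half credit for exact ties:
#' \deqn{A = (1 / (n_+ n_-)) \sum_{i,j} [x_i > y_j] + 0.5 [x_i = y_j].}
#' Computed through mid-ranks, which equals exhaustive pair counting
#' exactly and matches the trapezoidal area under the empirical ROC curve.
#'
#' @param scoresPos scores of the positive cases.
#' @param scoresNeg scores of the negative cases.
#' @return AUC in [0, 1].
#' @examples
#' aucMannWhitney(c(0.9, 0.4), c(0.5, 0.1))   # 0.75
#' @export
aucMannWhitney <- function(scoresPos, scoresNeg) {
  m <- length(scoresPos); n <- length(scoresNeg)
  if (m == 0L || n == 0L) stop("both classes must be non-empty")
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc data frame from \code{\link{rocPoints}}.
#' @return Area in [0, 1].
#' @export
rocAuc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Stratified bootstrap percentile CI for an observer's AUC
#'
#' Resamples subjects with replacement within each truth class (so no
#' replicate ever loses a class), recomputes the Mann-Whitney AUC, and
#' takes the percentile interval.  Fully reproducible from the seed.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param rater rater identifier.
#' @param nBoot bootstrap replicates (default 2000, minimum 100).
#' @param confLevel confidence level (default 0.95).
#' @param seed integer seed for the resampling stream.
#' @return List with \code{auc}, \code{ci_lower}, \code{ci_upper},
#'   \code{n_boot}, \code{seed}.
#' @export
bootstrapAucCi <- function(x, rater, nBoot = 2000, confLevel = 0.95,
                           seed = 1L) {
  stopifnot(nBoot >= 100)
  s <- adScores(x, rater)
  y <- truthLabels(x) == positiveCode(categorySet(x))
  if (!any(y) || all(y)) stop("both classes must be present")
  pos <- s[y]; neg <- s[!y]
  reps <- withLocalSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      aucMannWhitney(sample(pos, replace = TRUE),
                     sample(neg, replace = TRUE))
    }, numeric(1L))
  })
  qs <- unname(quantile(reps, c((1 - confLevel) / 2, (1 + confLevel) / 2)))
  list(auc = aucMannWhitney(pos, neg), ci_lower = qs[1L], ci_upper = qs[2L],
       n_boot = nBoot, seed = as.integer(seed))
}

# Placement values: for each positive case, the fraction of negatives it
# outranks (ties half); and symmetrically for negatives.
placementValues <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp))
}

#' DeLong's test for two correlated AUCs
#'
#' Nonparametric comparison of two observers' AUCs measured on the same
#' subjects.  Each observer's AUC is the mean of its positive-case
#' placement values; the variance of the AUC difference combines the
#' empirical covariance matrices of the paired placement vectors:
#' \deqn{Var(\Delta) = (S^{10}_{aa} + S^{10}_{bb} - 2 S^{10}_{ab})/n_+ +
#'       (S^{01}_{aa} + S^{01}_{bb} - 2 S^{01}_{ab})/n_-}
#' with a two-sided normal p-value for z = Delta / sqrt(Var).
#'
#' @param scoresA,scoresB score vectors of the two observers, aligned to
#'   the same subjects.
#' @param labels logical or 0/1 truth vector.
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta},
#'   \code{variance_delta}, \code{z}, \code{p}; when the variance is zero
#'   (e.g. identical score vectors) \code{z} and \code{p} are \code{NA}
#'   with a \code{reason}.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pa <- placementValues(scoresA[labels], scoresA[!labels])
  pb <- placementValues(scoresB[labels], scoresB[!labels])
  aucA <- mean(pa$v10); aucB <- mean(pb$v10)
  m <- sum(labels); n <- sum(!labels)
  s10 <- if (m > 1) var(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) var(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  out <- list(auc_a = aucA, auc_b = aucB, delta = aucA - aucB,
              variance_delta = vd)
  if (vd <= 0) {
    und <- undefinedStat(c("z", "p"),
                         "zero variance of the AUC difference")
    return(c(out, und))
  }
  z <- out$delta / sqrt(vd)
  c(out, list(z = z, p = 2 * pnorm(-abs(z))))
}

#' Single-observer DeLong variance of an AUC
#'
#' Variance of one empirical AUC from the placement-value decomposition;
#' zero for perfectly separated data.
#'
#' @inheritParams rocPoints
#' @return Non-negative variance estimate.
#' @export
delongAucVariance <- function(scores, labels) {
  labels <- as.logical(labels)
  p <- placementValues(scores[labels], scores[!labels])
  m <- sum(labels); n <- sum(!labels)
  (if (m > 1) var(p$v10) else 0) / m + (if (n > 1) var(p$v01) else 0) / n
}
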