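#' Tie-tolerant highest-probability credit assignment
#'
#' Converts one probability vector into a fractional label assignment: the
#' categories whose value lies within \code{tieTolerance} of the maximum
#' form the tie set of size k, and each receives credit 1/k; all other
#' categories receive 0.  A unique maximum therefore yields a unit vector.
#' With \code{digits} set, values are first rounded to that many decimals
#' before comparison ("reported-precision" mode): scores recorded at, say,
#' one-decimal percent then tie exactly, while raw floating-point model
#' outputs essentially never do.
#'
#' @param p named numeric probability vector over the categories.
#' @param tieTolerance additive tolerance defining a tie (default 1e-9).
#' @param digits optional decimals to round to before tie detection.
#' @return Named numeric credit vector summing to exactly 1.
#' @examples
#' p <- c(CN = 0.257, AD = 0.743, BVFTD = 0, SD = 0, PNFA = 0, PSP = 0,
#'        DLB = 0)
#' assignCredit(p)                      # unit credit on AD
#' p2 <- c(CN = 0.3, AD = 0.3, BVFTD = 0.3, SD = 0.1, PNFA = 0, PSP = 0,
#'         DLB = 0)
#' assignCredit(p2)                     # 1/3 on each tied category
#' @export
assignCredit <- function(p, tieTolerance = 1e-9, digits = NULL) {
  stopifnot(is.numeric(p), length(p) >= 1L, tieTolerance >= 0)
  q <- if (is.null(digits)) p else round(p, digits)
  tied <- q >= max(q) - tieTolerance
  credit <- numeric(length(p))
  credit[tied] <- 1 / sum(tied)
  names(credit) <- names(p)
  credit
}

#' Partial-credit score of one case
#'
#' The case is fully correct (1) when the true category uniquely holds the
#' highest probability, partially correct (1/k) when it is among k tied
#' top categories, and incorrect (0) otherwise.
#'
#' @param credit credit vector from \code{\link{assignCredit}}.
#' @param truth true category code.
#' @return Score in [0, 1].
#' @export
scoreCase <- function(credit, truth) {
  if (!truth %in% names(credit)) stop("truth label not among categories")
  unname(credit[truth])
}

#' Per-case credit matrix for one rater
#'
#' Applies \code{\link{assignCredit}} to every subject's probability vector
#' for the given rater, returning the subjects x categories matrix of
#' fractional assignments on which the confusion matrix, partial-credit
#' metrics and tie-aware kappa are built.
#'
#' @inheritParams fractionalConfusion
#' @return Numeric matrix, one row per subject, rows summing to 1.
#' @export
creditMatrix <- function(x, rater, tieTolerance = 1e-9, digits = NULL) {
  pm <- raterProbs(x, rater)
  cm <- t(apply(pm, 1L, assignCredit, tieTolerance = tieTolerance,
                digits = digits))
  dimnames(cm) <- dimnames(pm)
  cm
}

#' Fractional confusion matrix under partial-credit scoring
#'
#' Tabulates highest-probability assignments by true label: entry
#' (t, c) is the total credit mass that subjects with truth t put on
#' predicted category c.  Tied top probabilities contribute equal
#' fractional counts to each tied column, so rows sum exactly to the class
#' sizes and the total mass equals the number of subjects.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param rater rater identifier.
#' @param tieTolerance,digits passed to \code{\link{assignCredit}}.
#' @return Matrix with one row per truth class present (in category order)
#'   and one column per category; attributes \code{positive} and
#'   \code{negative} record the binary-collapse codes.
#' @export
fractionalConfusion <- function(x, rater, tieTolerance = 1e-9,
                                digits = NULL) {
  cm <- creditMatrix(x, rater, tieTolerance, digits)
  truth <- truthLabels(x)
  codes <- categoryCodes(categorySet(x))
  classes <- codes[codes %in% unique(truth)]
  out <- t(vapply(classes,
                  function(t) colSums(cm[truth == t, , drop = FALSE]),
                  numeric(ncol(cm))))
  dimnames(out) <- list(truth = classes, predicted = codes)
  attr(out, "positive") <- positiveCode(categorySet(x))
  attr(out, "negative") <- negativeCode(categorySet(x))
  out
}

#' Wilson score interval for a (possibly fractional) proportion
#'
#' Standard Wilson interval evaluated at \code{p = successes/n} with the
#' normal quantile at \code{(1 + confLevel)/2}; bounds clamped to [0, 1].
#' Fractional success counts from partial-credit scoring substitute
#' directly into the formula.
#'
#' @param successes non-negative success mass (may be fractional).
#' @param n number of trials (> 0).
#' @param confLevel confidence level (default 0.95).
#' @return Named vector \code{c(lower, upper)}.
#' @examples
#' wilsonInterval(5, 10)        # approx (0.237, 0.763)
#' wilsonInterval(1.5, 2)       # fractional successes from a tie
#' @export
wilsonInterval <- function(successes, n, confLevel = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n + 1e-9,
            confLevel > 0, confLevel < 1)
  z <- qnorm((1 + confLevel) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Wald (normal-approximation) interval for a proportion
#'
#' Symmetric interval \code{p +/- z * sqrt(p(1-p)/n)}, clamped to [0, 1].
#' Provided because symmetric printed intervals in small reader studies are
#' often Wald even when Wilson is named; Wilson is the package default.
#'
#' @inheritParams wilsonInterval
#' @return Named vector \code{c(lower, upper)}.
#' @export
waldInterval <- function(successes, n, confLevel = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n + 1e-9)
  z <- qnorm((1 + confLevel) / 2)
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

#' Binary classification metrics from a fractional confusion matrix
#'
#' Collapses the multi-class tabulation to the disease-vs-normal outcome:
#' accuracy = (mass on (pos,pos) + mass on (neg,neg)) / N, sensitivity =
#' mass on (pos,pos) / n_pos, specificity = mass on (neg,neg) / n_neg.
#' Credit mass a rater places on any other category counts against all
#' three (a top pick outside the binary pair is a misclassification).
#' Confidence intervals substitute the fractional success mass into the
#' Wilson (default) or Wald formula.
#'
#' @param m matrix from \code{\link{fractionalConfusion}}.
#' @param confLevel confidence level (default 0.95).
#' @param ciMethod \code{"wilson"} (default) or \code{"wald"}.
#' @return List with \code{accuracy}, \code{sensitivity}, \code{specificity}
#'   (each \code{list(estimate, lower, upper)}), \code{n_pos}, \code{n_neg}.
#' @export
classificationMetrics <- function(m, confLevel = 0.95,
                                  ciMethod = c("wilson", "wald")) {
  ciMethod <- match.arg(ciMethod)
  pos <- attr(m, "positive"); neg <- attr(m, "negative")
  if (!all(c(pos, neg) %in% rownames(m)))
    stop("confusion matrix must contain both the positive and negative ",
         "truth classes")
  ci <- if (ciMethod == "wilson") wilsonInterval else waldInterval
  nPos <- sum(m[pos, ]); nNeg <- sum(m[neg, ]); n <- sum(m)
  if (nPos <= 0 || nNeg <= 0) stop("a required truth class has no subjects")
  prop <- function(successes, total) {
    b <- ci(successes, total, confLevel)
    list(estimate = successes / total, lower = unname(b["lower"]),
         upper = unname(b["upper"]))
  }
  list(accuracy = prop(m[pos, pos] + m[neg, neg], n),
       sensitivity = prop(m[pos, pos], nPos),
       specificity = prop(m[neg, neg], nNeg),
       n_pos = nPos, n_neg = nNeg)
}

#' Weighted F1 score over the truth classes
#'
#' For each truth class c: precision = diagonal mass / column total (0 when
#' the column is empty), recall = diagonal mass / row total, F1 their
#' harmonic mean (0 when both vanish); the weighted score averages the
#' per-class F1 with weights proportional to class size.  All seven
#' predicted columns enter the precision denominators, so off-pair leakage
#' is penalized, while only classes present in the truth contribute terms.
#'
#' @param m matrix from \code{\link{fractionalConfusion}}.
#' @return Weighted F1 in [0, 1].
#' @export
weightedF1 <- function(m) {
  n <- sum(m)
  colTot <- colSums(m)
  f1 <- vapply(rownames(m), function(cl) {
    tp <- m[cl, cl]
    prec <- if (colTot[cl] > 0) tp / colTot[cl] else 0
    rec <- tp / sum(m[cl, ])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1L))
  sum(rowSums(m) / n * f1)
}

#' Tie-aware Cohen's kappa
#'
#' Chance-corrected agreement between two sets of fractional label
#' assignments.  Observed agreement is the mean per-case dot product of
#' the two credit vectors (a case where one observer splits CN/AD and the
#' other commits to AD contributes 1/2); expected agreement is the dot
#' product of the two observers' mean credit profiles.  With no ties this
#' reduces exactly to classical Cohen's kappa on hard labels.  Truth can be
#' supplied as a character vector, which is encoded as unit credit vectors.
#'
#' @param a,b credit matrices (cases x categories, from
#'   \code{\link{creditMatrix}}) or character label vectors.
#' @param categories category codes used to encode character labels;
#'   defaults to the union of columns/labels seen.
#' @return List with \code{kappa}, \code{p_o}, \code{p_e}; when both
#'   observers are degenerate on the same single category (\code{p_e = 1})
#'   kappa is undefined and returned as \code{NA} with a \code{reason}.
#' @examples
#' a <- c("CN", "CN", "AD", "AD"); b <- c("CN", "AD", "AD", "AD")
#' tieAwareKappa(a, b)$kappa    # 0.5
#' @export
tieAwareKappa <- function(a, b, categories = NULL) {
  isLab <- function(v) is.character(v) || is.factor(v)
  if (is.null(categories)) {
    seen <- c(if (isLab(a)) as.character(a), if (isLab(b)) as.character(b),
              if (!isLab(a)) colnames(as.matrix(a)),
              if (!isLab(b)) colnames(as.matrix(b)))
    categories <- unique(seen)
  }
  enc <- function(v) {
    if (!isLab(v)) return(as.matrix(v))
    v <- as.character(v)
    m <- matrix(0, length(v), length(categories),
                dimnames = list(NULL, categories))
    m[cbind(seq_along(v), match(v, categories))] <- 1
    m
  }
  A <- enc(a); B <- enc(b)
  if (nrow(A) != nrow(B)) stop("'a' and 'b' must score the same cases")
  if (nrow(A) < 2L) stop("kappa needs at least 2 cases")
  if (!is.null(colnames(A)) && !is.null(colnames(B))) {
    common <- union(colnames(A), colnames(B))
    pad <- function(M) {
      out <- matrix(0, nrow(M), length(common),
                    dimnames = list(rownames(M), common))
      out[, colnames(M)] <- M
      out
    }
    A <- pad(A); B <- pad(B)
  }
  po <- mean(rowSums(A * B))
  pe <- sum(colMeans(A) * colMeans(B))
  if (abs(1 - pe) < 1e-12)
    return(undefinedStat(c("kappa"), "expected agreement is 1 (both observers degenerate on one identical category)"))
  list(kappa = (po - pe) / (1 - pe), p_o = po, p_e = pe)
}
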