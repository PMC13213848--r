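#' Brier score of disease-probability forecasts
#'
#' Mean squared error between predicted disease probabilities and the
#' binary outcome (1 = disease); 0 is perfect, 0.25 is the constant-0.5
#' forecast.
#'
#' @param probs numeric vector of predicted probabilities.
#' @param labels logical or 0/1 outcome vector.
#' @return Brier score in [0, 1].
#' @export
brierScore <- function(probs, labels) {
  labels <- as.numeric(as.logical(labels))
  stopifnot(length(probs) == length(labels), length(probs) >= 1L)
  mean((probs - labels)^2)
}

#' Calibration curve (reliability diagram data)
#'
#' Partitions cases by predicted probability into \code{nBins} bins
#' (equal-width over [0, 1] by default, or quantile-based) and reports the
#' mean prediction, the observed fraction of positive outcomes, and the
#' count per non-empty bin.  Bins are half-open [lo, hi) with the last bin
#' closed, so every case lands in exactly one bin.
#'
#' @inheritParams brierScore
#' @param nBins number of bins (>= 2, default 5).
#' @param strategy \code{"width"} (equal-width, default) or
#'   \code{"quantile"}.
#' @return Data frame with columns \code{mean_predicted},
#'   \code{observed_fraction}, \code{count}; counts sum to the number of
#'   cases.
#' @export
calibrationCurve <- function(probs, labels, nBins = 5,
                             strategy = c("width", "quantile")) {
  strategy <- match.arg(strategy)
  labels <- as.numeric(as.logical(labels))
  stopifnot(length(probs) == length(labels), nBins >= 2)
  edges <- if (strategy == "width") {
    seq(0, 1, length.out = nBins + 1)
  } else {
    unique(quantile(probs, seq(0, 1, length.out = nBins + 1), names = FALSE))
  }
  bin <- findInterval(probs, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  agg <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(mean_predicted = mean(probs[i]),
               observed_fraction = mean(labels[i]),
               count = sum(i))
  })
  do.call(rbind, agg)
}

#' Net benefit of probability-guided diagnosis at one threshold
#'
#' Decision-analytic utility of calling disease when the predicted
#' probability reaches the threshold probability p_t:
#' \deqn{NB(p_t) = TP/N - (FP/N) \cdot p_t / (1 - p_t).}
#' The treat-all reference is \code{prevalence - (1 - prevalence) *
#' p_t / (1 - p_t)} and treat-none is identically 0.
#'
#' @inheritParams brierScore
#' @param pT threshold probability, strictly inside (0, 1).
#' @return Net benefit (can be negative).
#' @export
netBenefit <- function(probs, labels, pT) {
  stopifnot(pT > 0, pT < 1)
  labels <- as.logical(labels)
  stopifnot(length(probs) == length(labels))
  call <- probs >= pT
  n <- length(labels)
  sum(call & labels) / n - sum(call & !labels) / n * pT / (1 - pT)
}

#' Decision curve over a threshold grid
#'
#' Evaluates \code{\link{netBenefit}} for each requested rater at every
#' threshold probability in the grid, alongside the treat-all and
#' treat-none references, and flags per rater whether the net benefit is
#' strictly positive over the whole clinically quoted [0.1, 0.9] subrange.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param raters rater identifiers (default: all).
#' @param grid threshold probabilities, all inside (0, 1); default 0.01
#'   steps over [0.05, 0.95].
#' @return List with a data frame \code{curve} (columns \code{threshold},
#'   \code{treat_all}, \code{treat_none}, one column per rater) and a named
#'   logical vector \code{positive_over_0.1_0.9}.
#' @export
decisionCurve <- function(x, raters = raterNames(x),
                          grid = seq(0.05, 0.95, by = 0.01)) {
  stopifnot(all(grid > 0), all(grid < 1))
  y <- truthLabels(x) == positiveCode(categorySet(x))
  prev <- mean(y)
  curve <- data.frame(threshold = grid,
                      treat_all = prev - (1 - prev) * grid / (1 - grid),
                      treat_none = 0)
  for (r in raters) {
    s <- adScores(x, r)
    curve[[r]] <- vapply(grid, function(pt) netBenefit(s, y, pt),
                         numeric(1L))
  }
  sub <- grid >= 0.1 & grid <= 0.9
  flag <- vapply(raters, function(r) all(curve[[r]][sub] > 0), logical(1L))
  list(curve = curve, positive_over_0.1_0.9 = flag)
}
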