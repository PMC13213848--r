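# Fixture builders and independent brute-force oracles used across tests.

CODES <- categoryCodes(defaultCategories())

# Random study: uniform-Dirichlet probability vectors; with probability
# tieRate a case's top two categories are set exactly equal.
randomStudy <- function(nSub, nRaters = 1L, tieRate = 0, seed = 1L) {
  set.seed(seed)
  truth <- character(nSub)
  truth[] <- sample(c("AD", "CN"), nSub, replace = TRUE)
  truth[1L] <- "AD"; truth[2L] <- "CN"   # both classes always present
  arr <- array(0, dim = c(nSub, nRaters, length(CODES)),
               dimnames = list(sprintf("S%03d", seq_len(nSub)),
                               sprintf("R%d", seq_len(nRaters)), CODES))
  for (i in seq_len(nSub)) for (j in seq_len(nRaters)) {
    v <- runif(length(CODES))
    v <- v / sum(v)
    if (runif(1L) < tieRate) {
      top <- order(v, decreasing = TRUE)[1:2]
      v[top] <- mean(v[top])
    }
    arr[i, j, ] <- v
  }
  AssessmentTable(arr, truth = truth)
}

# Per-case loop oracle for the fractional confusion matrix: no vectorized
# shortcuts, ties found by direct comparison to the maximum.
bruteConfusion <- function(x, rater, tieTolerance = 1e-9) {
  truth <- truthLabels(x)
  pm <- raterProbs(x, rater)
  classes <- CODES[CODES %in% unique(truth)]
  out <- matrix(0, length(classes), length(CODES),
                dimnames = list(classes, CODES))
  for (i in seq_len(nrow(pm))) {
    tied <- which(pm[i, ] >= max(pm[i, ]) - tieTolerance)
    for (k in tied)
      out[truth[i], k] <- out[truth[i], k] + 1 / length(tied)
  }
  out
}

# Classical integer-count metrics, valid when no case is tied.
classicalMetrics <- function(x, rater) {
  truth <- truthLabels(x)
  pred <- apply(raterProbs(x, rater), 1L, function(v) CODES[which.max(v)])
  list(accuracy = mean((truth == "AD" & pred == "AD") |
                         (truth == "CN" & pred == "CN")),
       sensitivity = mean(pred[truth == "AD"] == "AD"),
       specificity = mean(pred[truth == "CN"] == "CN"))
}

# Exhaustive pair-counting AUC oracle.
bruteAuc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Single-observer study with prescribed AD scores (rest of the mass on CN).
scoreStudy <- function(scores, labels) {
  n <- length(scores)
  arr <- array(0, dim = c(n, 1L, length(CODES)),
               dimnames = list(sprintf("S%03d", seq_len(n)), "R1", CODES))
  arr[, 1L, "AD"] <- scores
  arr[, 1L, "CN"] <- 1 - scores
  AssessmentTable(arr, truth = ifelse(as.logical(labels), "AD", "CN"))
}
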