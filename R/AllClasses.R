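#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats anova aov cor cor.test lm pf plogis pnorm pt qnorm
#'   quantile rbinom rnorm runif sd var
#' @importFrom utils packageVersion read.csv write.csv
NULL

#' Ordered set of diagnostic categories
#'
#' Holds the ordered category codes a study scores over, together with the
#' two codes used when the analysis is collapsed to a binary
#' disease-vs-normal outcome.  The default set is the seven-category
#' dementia differential (CN, AD, BVFTD, SD, PNFA, PSP, DLB) with AD as the
#' positive (disease) class and CN as the negative (normal) class.
#'
#' @slot codes ordered character vector of unique category codes.
#' @slot positive code of the disease class for the binary collapse.
#' @slot negative code of the normal class for the binary collapse.
#'
#' @aliases CategorySet-class
#' @exportClass CategorySet
setClass("CategorySet",
  representation(codes = "character", positive = "character",
                 negative = "character"))

setValidity("CategorySet", function(object) {
  msg <- character()
  if (length(object@codes) == 0L)
    msg <- c(msg, "'codes' must be non-empty")
  if (anyDuplicated(object@codes))
    msg <- c(msg, "'codes' must be unique")
  if (length(object@positive) != 1L || !object@positive %in% object@codes)
    msg <- c(msg, "'positive' must be a single member of 'codes'")
  if (length(object@negative) != 1L || !object@negative %in% object@codes)
    msg <- c(msg, "'negative' must be a single member of 'codes'")
  if (length(object@positive) == 1L && length(object@negative) == 1L &&
      identical(object@positive, object@negative))
    msg <- c(msg, "'positive' and 'negative' must differ")
  if (length(msg)) msg else TRUE
})

#' Construct a CategorySet
#'
#' @param codes ordered character vector of unique category codes.
#' @param positive disease-class code for binary metrics (default \code{"AD"}).
#' @param negative normal-class code for binary metrics (default \code{"CN"}).
#' @return A \linkS4class{CategorySet}.
#' @examples
#' defaultCategories()
#' CategorySet(c("HEALTHY", "SICK"), positive = "SICK", negative = "HEALTHY")
#' @export
CategorySet <- function(codes, positive = "AD", negative = "CN") {
  new("CategorySet", codes = as.character(codes),
      positive = positive, negative = negative)
}

#' @rdname CategorySet
#' @export
defaultCategories <- function() {
  CategorySet(c("CN", "AD", "BVFTD", "SD", "PNFA", "PSP", "DLB"),
              positive = "AD", negative = "CN")
}

#' @describeIn CategorySet ordered codes.
#' @param x a \code{CategorySet}.
#' @export
categoryCodes <- function(x) x@codes

#' @describeIn CategorySet positive (disease) code.
#' @export
positiveCode <- function(x) x@positive

#' @describeIn CategorySet negative (normal) code.
#' @export
negativeCode <- function(x) x@negative

setMethod("show", "CategorySet", function(object) {
  cat("CategorySet with", length(object@codes), "categories:",
      paste(object@codes, collapse = ", "), "\n")
  cat("  positive:", object@positive, " negative:", object@negative, "\n")
})

#' Multi-rater probabilistic assessment table
#'
#' The central container of a reader study: a complete subjects-by-raters
#' grid in which every cell is a probability vector over the study's
#' diagnostic categories, plus a ground-truth label per subject.  The class
#' extends \link[SummarizedExperiment]{SummarizedExperiment}: one assay per
#' category (each a subjects x raters matrix), subjects as rows, raters as
#' columns, and the truth labels in \code{rowData(x)$truth}.
#'
#' Validity requires a complete grid, non-negative values, per-cell
#' probability mass of 1 within 1e-6, and truth labels drawn from the
#' category codes.
#'
#' @aliases AssessmentTable-class
#' @exportClass AssessmentTable
setClass("AssessmentTable",
  contains = "SummarizedExperiment",
  representation(categories = "CategorySet"))

setValidity("AssessmentTable", function(object) {
  msg <- character()
  codes <- categoryCodes(object@categories)
  anames <- SummarizedExperiment::assayNames(object)
  if (!identical(anames, codes))
    msg <- c(msg, "assay names must equal the category codes, in order")
  rd <- SummarizedExperiment::rowData(object)
  if (!"truth" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'truth' column")
  } else if (!all(rd$truth %in% codes)) {
    msg <- c(msg, "every truth label must be a category code")
  }
  if (length(msg) == 0L && length(anames) > 0L && nrow(object) > 0L) {
    tot <- Reduce(`+`, SummarizedExperiment::assays(object))
    if (any(vapply(SummarizedExperiment::assays(object),
                   function(a) any(a < 0), logical(1L))))
      msg <- c(msg, "probabilities must be non-negative")
    if (any(abs(tot - 1) > 1e-6))
      msg <- c(msg, "each probability vector must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssessmentTable
#'
#' @param probs a 3-dimensional numeric array with dimensions
#'   \code{subjects x raters x categories} (dimnames required on all three
#'   margins), or a named list of subjects x raters matrices, one per
#'   category in order.
#' @param truth character vector of ground-truth labels, one per subject,
#'   each a member of the category codes.
#' @param categories a \linkS4class{CategorySet}
#'   (default \code{defaultCategories()}).
#' @param normalize divide each probability vector by its total mass before
#'   validation (default \code{TRUE}); vectors with zero mass are an error.
#' @return An \linkS4class{AssessmentTable}.
#' @examples
#' cats <- defaultCategories()
#' pr <- array(0, dim = c(2, 1, 7),
#'             dimnames = list(c("s1", "s2"), "raterA", categoryCodes(cats)))
#' pr["s1", 1, "AD"] <- 0.743; pr["s1", 1, "CN"] <- 0.257
#' pr["s2", 1, "CN"] <- 1
#' at <- AssessmentTable(pr, truth = c("AD", "CN"))
#' adScores(at, "raterA")
#' @export
AssessmentTable <- function(probs, truth, categories = defaultCategories(),
                            normalize = TRUE) {
  codes <- categoryCodes(categories)
  if (is.list(probs)) {
    if (!identical(names(probs), codes))
      stop("list 'probs' must be named by the category codes, in order")
    probs <- array(unlist(probs, use.names = FALSE),
                   dim = c(nrow(probs[[1L]]), ncol(probs[[1L]]),
                           length(codes)),
                   dimnames = c(dimnames(probs[[1L]]), list(codes)))
  }
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  if (is.null(dimnames(probs)[[3L]])) dimnames(probs)[[3L]] <- codes
  if (!identical(dimnames(probs)[[3L]], codes))
    stop("third dimension of 'probs' must be the category codes, in order")
  if (is.null(dimnames(probs)[[1L]]))
    dimnames(probs)[[1L]] <- sprintf("S%03d", seq_len(dim(probs)[1L]))
  if (is.null(dimnames(probs)[[2L]]))
    dimnames(probs)[[2L]] <- sprintf("rater%d", seq_len(dim(probs)[2L]))
  if (normalize) {
    tot <- apply(probs, c(1L, 2L), sum)
    if (any(tot <= 0))
      stop("probability vector with no mass cannot be normalized")
    probs <- sweep(probs, c(1L, 2L), tot, "/")
  }
  assays <- lapply(seq_along(codes), function(k) probs[, , k, drop = TRUE])
  if (dim(probs)[1L] == 1L || dim(probs)[2L] == 1L)
    assays <- lapply(seq_along(codes), function(k)
      matrix(probs[, , k], dim(probs)[1L], dim(probs)[2L],
             dimnames = dimnames(probs)[1:2]))
  names(assays) <- codes
  truth <- as.character(truth)
  if (length(truth) != dim(probs)[1L])
    stop("'truth' must have one label per subject")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(truth = truth,
                                   row.names = dimnames(probs)[[1L]]))
  new("AssessmentTable", se, categories = categories)
}

setMethod("show", "AssessmentTable", function(object) {
  cats <- object@categories
  tr <- truthLabels(object)
  cat("AssessmentTable:", nrow(object), "subjects x", ncol(object),
      "raters x", length(categoryCodes(cats)), "categories\n")
  cat("  categories:", paste(categoryCodes(cats), collapse = ", "), "\n")
  cat("  raters:", paste(colnames(object), collapse = ", "), "\n")
  cat("  truth: ", sum(tr == positiveCode(cats)), " ", positiveCode(cats),
      " / ", sum(tr == negativeCode(cats)), " ", negativeCode(cats), sep = "")
  other <- sum(!tr %in% c(positiveCode(cats), negativeCode(cats)))
  if (other > 0) cat(" /", other, "other")
  cat("\n")
})

#' Accessors for AssessmentTable
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param rater a rater identifier (column name).
#' @return \code{truthLabels}: character vector of per-subject truth labels.
#'   \code{raterNames} / \code{subjectIds}: character vectors.
#'   \code{categorySet}: the table's \linkS4class{CategorySet}.
#'   \code{raterProbs}: subjects x categories numeric matrix for one rater.
#'   \code{adScores}: numeric vector of the positive-class (disease)
#'   probability per subject for one rater.
#' @name AssessmentTable-accessors
NULL

#' @rdname AssessmentTable-accessors
#' @export
truthLabels <- function(x) SummarizedExperiment::rowData(x)$truth

#' @rdname AssessmentTable-accessors
#' @export
raterNames <- function(x) colnames(x)

#' @rdname AssessmentTable-accessors
#' @export
subjectIds <- function(x) rownames(x)

#' @rdname AssessmentTable-accessors
#' @export
categorySet <- function(x) x@categories

#' @rdname AssessmentTable-accessors
#' @export
raterProbs <- function(x, rater) {
  if (!rater %in% colnames(x))
    stop("unknown rater: ", rater)
  codes <- categoryCodes(x@categories)
  m <- vapply(codes,
              function(k) SummarizedExperiment::assay(x, k)[, rater],
              numeric(nrow(x)))
  if (nrow(x) == 1L) m <- matrix(m, 1L, length(codes),
                                 dimnames = list(rownames(x), codes))
  m
}

#' @rdname AssessmentTable-accessors
#' @export
adScores <- function(x, rater) {
  raterProbs(x, rater)[, positiveCode(x@categories)]
}

#' Container for a full study evaluation
#'
#' Nested-list report holding every statistic a full run computes:
#' per-rater classification metrics, pairwise agreement, per-rater
#' discrimination, calibration and decision-curve blocks, pairwise DeLong
#' tests, the power analysis, and provenance (seed, parameter digest,
#' package version).  Statistics that are undefined on the data (for
#' example a correlation of a constant score vector) are stored as
#' \code{NA} with a sibling \code{reason} string and serialized as JSON
#' \code{null}.
#'
#' @slot report named nested list of results.
#' @aliases MetricReport-class
#' @exportClass MetricReport
setClass("MetricReport", representation(report = "list"))

#' @describeIn MetricReport-class the underlying nested list.
#' @param x a \code{MetricReport}.
#' @export
reportData <- function(x) x@report

setMethod("show", "MetricReport", function(object) {
  r <- object@report
  cat("MetricReport (raterDx ", r$provenance$package_version, ")\n",
      sep = "")
  cat("  raters:", paste(names(r$classification), collapse = ", "), "\n")
  for (nm in names(r$classification)) {
    cl <- r$classification[[nm]]
    di <- r$discrimination[[nm]]
    cat(sprintf("  %-14s acc %.2f  sens %.2f  spec %.2f  AUC %.3f  Brier %.3f\n",
                nm, cl$accuracy$estimate, cl$sensitivity$estimate,
                cl$specificity$estimate, di$auc$auc, di$brier))
  }
  cat("  pairwise blocks:", length(r$agreement), "agreement,",
      length(r$delong), "DeLong\n")
})
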