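#' Read a rater-assessment study from CSV files
#'
#' Reads the long-format assessment file (one row per subject-rater pair,
#' header \code{subject_id,rater_id,<one column per category>}) and the
#' truth file (header \code{subject_id,truth}) and returns a validated
#' \linkS4class{AssessmentTable}.  Category columns are matched
#' case-insensitively against the category codes; extra columns are an
#' error, as are duplicate or missing subject-rater pairs (the design is a
#' complete grid).  The probability scale is declared, never guessed:
#' \code{scale = "percent"} divides by 100 before normalization,
#' \code{scale = "fraction"} uses values as-is, and \code{scale = "auto"}
#' (explicit opt-in) infers percent when the median row total exceeds 50.
#'
#' @param csvPath path to the assessment CSV.
#' @param truthPath path to the truth CSV.
#' @param scale \code{"fraction"}, \code{"percent"} or \code{"auto"}.
#' @param sumTolerance maximum allowed deviation of a row total from the
#'   expected total mass, as a fraction of that mass (default 0.005, i.e.
#'   0.5 percentage points on percent input).
#' @param categories a \linkS4class{CategorySet}.
#' @return An \linkS4class{AssessmentTable}; rows keep file order.
#' @examples
#' csv <- system.file("extdata", "example_assessments.csv", package = "raterDx")
#' tru <- system.file("extdata", "example_truth.csv", package = "raterDx")
#' readAssessments(csv, tru, scale = "percent")
#' @export
readAssessments <- function(csvPath, truthPath,
                            scale = c("fraction", "percent", "auto"),
                            sumTolerance = 0.005,
                            categories = defaultCategories()) {
  scale <- match.arg(scale)
  codes <- categoryCodes(categories)
  df <- read.csv(csvPath, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("subject_id", "rater_id")
  if (!all(req %in% names(df)))
    stop("assessment CSV must have 'subject_id' and 'rater_id' columns")
  probCols <- setdiff(names(df), req)
  matched <- match(toupper(probCols), toupper(codes))
  if (anyNA(matched))
    stop("unexpected column(s) in assessment CSV: ",
         paste(probCols[is.na(matched)], collapse = ", "))
  if (length(probCols) != length(codes) || anyDuplicated(matched))
    stop("assessment CSV must have exactly one column per category")
  probCols <- probCols[order(matched)]   # file columns in category order

  key <- paste(df$subject_id, df$rater_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, rater) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  subjects <- unique(as.character(df$subject_id))
  raters <- unique(as.character(df$rater_id))
  if (nrow(df) != length(subjects) * length(raters))
    stop("incomplete grid: every subject must be scored by every rater")

  pm <- as.matrix(df[probCols])
  storage.mode(pm) <- "double"
  if (anyNA(pm)) stop("missing probability value(s)")
  if (any(pm < 0)) stop("negative probability value(s)")
  expectedTotal <- switch(scale,
    fraction = 1,
    percent = 100,
    auto = if (stats::median(rowSums(pm)) > 50) 100 else 1)
  rowTot <- rowSums(pm)
  if (any(rowTot <= 0))
    stop("probability row with no mass cannot be normalized")
  bad <- abs(rowTot - expectedTotal) > sumTolerance * expectedTotal
  if (any(bad))
    stop("probability row total deviates from ", expectedTotal,
         " by more than tolerance for subject(s): ",
         paste(unique(df$subject_id[bad]), collapse = ", "))
  if (expectedTotal != 1) pm <- pm / expectedTotal

  arr <- array(NA_real_, dim = c(length(subjects), length(raters),
                                 length(codes)),
               dimnames = list(subjects, raters, codes))
  si <- match(as.character(df$subject_id), subjects)
  ri <- match(as.character(df$rater_id), raters)
  for (k in seq_along(codes))
    arr[cbind(si, ri, k)] <- pm[, k]

  tdf <- read.csv(truthPath, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "truth") %in% names(tdf)))
    stop("truth CSV must have 'subject_id' and 'truth' columns")
  ti <- match(subjects, as.character(tdf$subject_id))
  if (anyNA(ti))
    stop("truth missing for subject(s): ",
         paste(subjects[is.na(ti)], collapse = ", "))
  truth <- toupper(as.character(tdf$truth))[ti]
  if (!all(truth %in% codes))
    stop("truth label(s) outside the category set: ",
         paste(unique(truth[!truth %in% codes]), collapse = ", "))

  AssessmentTable(arr, truth = truth, categories = categories)
}

#' Write a study back to the CSV interchange format
#'
#' Writes the long-format assessment CSV and the truth CSV that
#' \code{\link{readAssessments}} reads, on the fraction scale at full
#' precision.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param csvPath,truthPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeAssessments <- function(x, csvPath, truthPath) {
  codes <- categoryCodes(categorySet(x))
  rows <- do.call(rbind, lapply(raterNames(x), function(r) {
    pm <- raterProbs(x, r)
    data.frame(subject_id = subjectIds(x), rater_id = r, pm,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(match(rows$subject_id, subjectIds(x))), , drop = FALSE]
  write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
            csvPath, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(subject_id = subjectIds(x), truth = truthLabels(x)),
            truthPath, row.names = FALSE, quote = FALSE)
  invisible(c(csvPath, truthPath))
}

#' Serialize a MetricReport to JSON
#'
#' Writes the report as a JSON document with stable key order and full
#' numeric precision; undefined statistics appear as \code{null} next to
#' their \code{reason} strings.  Identical reports produce byte-identical
#' files, so a seeded pipeline is reproducible at the file level.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  jsonlite::write_json(reportData(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null",
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Parse a MetricReport written by writeReport
#'
#' @param path path to the JSON file.
#' @return A \linkS4class{MetricReport} whose numeric leaves equal the
#'   written ones to full double precision.
#' @export
readReport <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  new("MetricReport", report = lst)
}
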