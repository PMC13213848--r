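#' Run the full evaluation pipeline on a study
#'
#' Executes, in order, every analysis the framework defines on a validated
#' assessment table: per-rater partial-credit scoring (fractional confusion
#' matrix, accuracy/sensitivity/specificity with Wilson and Wald intervals,
#' weighted F1, tie-aware kappa against truth), pairwise agreement
#' (Pearson, Spearman, ICC(A,1), kappa between raters, Bland-Altman,
#' Levene), per-rater discrimination (ROC points, Mann-Whitney AUC with
#' stratified bootstrap CI, DeLong variance), pairwise DeLong tests,
#' calibration (Brier, calibration curve) and decision-curve analysis, and
#' the correlated-AUC power analysis at the study's class sizes.  Every
#' statistic that is undefined on the data is reported as \code{NA} with a
#' reason, never dropped.  The whole run is reproducible from \code{seed}.
#'
#' @param x an \linkS4class{AssessmentTable}.
#' @param tieTolerance,digits tie handling, as in \code{\link{assignCredit}}.
#' @param confLevel confidence level for all intervals (default 0.95).
#' @param nBoot bootstrap replicates for AUC intervals (default 2000).
#' @param seed integer seed for every stochastic component.
#' @param calibrationBins,calibrationStrategy binning for
#'   \code{\link{calibrationCurve}}.
#' @param thresholdGrid grid for \code{\link{decisionCurve}}.
#' @param powerR,powerBaselineAuc,powerTarget assumptions for the power
#'   block (between-observer correlation, baseline AUC, target power).
#' @param verbose log one line per stage to the console.
#' @return A \linkS4class{MetricReport}.
#' @examples
#' at <- generateStudy(referenceConfig(), seed = 11)
#' rep <- runEvaluation(at, nBoot = 200, seed = 11, verbose = FALSE)
#' rep
#' @export
runEvaluation <- function(x, tieTolerance = 1e-9, digits = NULL,
                          confLevel = 0.95, nBoot = 2000, seed = 1L,
                          calibrationBins = 5,
                          calibrationStrategy = "width",
                          thresholdGrid = seq(0.05, 0.95, by = 0.01),
                          powerR = 0.5, powerBaselineAuc = 0.80,
                          powerTarget = 0.80, verbose = TRUE) {
  stopifnot(is(x, "AssessmentTable"))
  log <- function(...) if (verbose) message("[raterDx] ", ...)
  raters <- raterNames(x)
  cats <- categorySet(x)
  y <- truthLabels(x) == positiveCode(cats)
  truthCredit <- truthLabels(x)

  log("scoring ", length(raters), " raters")
  confusion <- list(); classification <- list()
  for (r in raters) {
    m <- fractionalConfusion(x, r, tieTolerance, digits)
    cl <- classificationMetrics(m, confLevel, "wilson")
    wald <- classificationMetrics(m, confLevel, "wald")
    cl$accuracy_wald <- wald$accuracy
    cl$sensitivity_wald <- wald$sensitivity
    cl$specificity_wald <- wald$specificity
    cl$weighted_f1 <- weightedF1(m)
    cl$kappa_vs_truth <- tieAwareKappa(
      creditMatrix(x, r, tieTolerance, digits), truthCredit,
      categories = categoryCodes(cats))
    confusion[[r]] <- data.frame(truth = rownames(m), as.data.frame(m),
                                 row.names = NULL, check.names = FALSE)
    classification[[r]] <- cl
  }

  log("pairwise agreement")
  pairs <- if (length(raters) >= 2L) utils::combn(raters, 2L) else
    matrix(character(), 2L, 0L)
  agreement <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    agreement[[paste(a, b, sep = "_vs_")]] <-
      pairwiseAgreement(x, a, b, tieTolerance, digits)
  }

  log("discrimination (", nBoot, " bootstrap replicates per rater)")
  discrimination <- list()
  for (i in seq_along(raters)) {
    r <- raters[i]
    s <- adScores(x, r)
    discrimination[[r]] <- list(
      auc = bootstrapAucCi(x, r, nBoot, confLevel,
                           seed = derivedSeed(seed, i)),
      delong_variance = delongAucVariance(s, y),
      roc = rocPoints(s, y),
      brier = brierScore(s, y),
      calibration = calibrationCurve(s, y, calibrationBins,
                                     calibrationStrategy))
  }

  log("pairwise DeLong tests")
  delong <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    delong[[paste(a, b, sep = "_vs_")]] <-
      delongTest(adScores(x, a), adScores(x, b), y)
  }

  log("decision curves")
  dca <- decisionCurve(x, raters, thresholdGrid)

  log("power analysis")
  powerBlock <- runPower(sum(y), sum(!y), r = powerR,
                         power = powerTarget,
                         baselineAuc = powerBaselineAuc,
                         method = "analytic", quiet = TRUE)

  params <- list(tie_tolerance = tieTolerance, digits = digits,
                 conf_level = confLevel, n_boot = nBoot, seed = seed,
                 calibration_bins = calibrationBins,
                 calibration_strategy = calibrationStrategy,
                 threshold_grid = range(thresholdGrid))
  report <- list(
    classification = classification,
    confusion = confusion,
    agreement = agreement,
    discrimination = discrimination,
    delong = delong,
    decision_curve = list(
      curve = dca$curve,
      positive_over_0.1_0.9 = as.list(dca$positive_over_0.1_0.9)),
    power = powerBlock,
    provenance = list(
      seed = as.integer(seed),
      config_digest = fnv1a(paste(deparse(params), collapse = "")),
      package_version = as.character(packageVersion("raterDx")),
      n_subjects = nrow(x), n_pos = sum(y), n_neg = sum(!y),
      raters = as.list(raters)))
  new("MetricReport", report = report)
}

#' Export a report's tabular blocks as CSV files
#'
#' Writes the per-rater fractional confusion matrices, ROC points and
#' calibration curves, the decision curve, and the Bland-Altman summary
#' table to a directory, one CSV per block, for external plotting.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
exportReportTables <- function(report, dir) {
  stopifnot(is(report, "MetricReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r <- reportData(report)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (nm in names(r$confusion))
    wr(r$confusion[[nm]], paste0("confusion_", nm, ".csv"))
  for (nm in names(r$discrimination)) {
    wr(r$discrimination[[nm]]$roc, paste0("roc_", nm, ".csv"))
    wr(r$discrimination[[nm]]$calibration,
       paste0("calibration_", nm, ".csv"))
  }
  wr(r$decision_curve$curve, "decision_curve.csv")
  ba <- do.call(rbind, lapply(names(r$agreement), function(p) {
    b <- r$agreement[[p]]$bland_altman
    data.frame(pair = p, mean_diff = b$mean_diff, sd_diff = b$sd_diff,
               loa_lower = b$loa_lower, loa_upper = b$loa_upper)
  }))
  if (!is.null(ba)) wr(ba, "bland_altman.csv")
  invisible(paths)
}
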