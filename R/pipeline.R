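#' @include io.R
NULL

.stateFromPrediction <- function(locomotion, posture) {
  ifelse(locomotion == "walking", "walking",
         c(stand = "standing", sit = "sitting",
           lay = "laying")[posture])
}

#' Process a whole synthetic cohort into labeled, localized windows
#'
#' Runs every simulated patient-day through the signal chain (windowing,
#' filtering, MAD, features), localizes each window from the beacon stream,
#' attaches the schedule ground truth, trains the hierarchical classifier on
#' the ground-truth labels of the training days (unless a fitted model is
#' supplied) and predicts activity labels for all windows.
#'
#' @param cohort A [SensorCohort-class] with simulated streams.
#' @param spec A [FilterSpec-class].
#' @param windowSec,overlapSec,madThreshold Signal-chain constants.
#' @param model Optional pre-trained [HierarchicalModel-class].
#' @param trainDays Day indices used for training when `model` is `NULL`
#'   (`NULL` = all days).
#' @param seed Training seed.
#' @return List with `windows` (one row per window: signal, location, truth
#'   and predicted label columns) and the `model` used.
#' @export
processCohort <- function(cohort, spec = filterSpec(), windowSec = 10,
                          overlapSec = 1, madThreshold = 0.02, model = NULL,
                          trainDays = NULL, seed = 1L) {
  keys <- names(accelStreams(cohort))
  if (!length(keys)) stop("cohort has no simulated streams")
  perDay <- list()
  for (key in keys) {
    st <- accelStreams(cohort)[[key]]
    w <- processAccelStream(st, spec, windowSec, overlapSec, madThreshold)
    if (!nrow(w)) next
    sch <- schedules(cohort)[[key]]
    gt <- windowGroundTruth(sch, w$startTime, windowSec)
    loc <- localizeWindows(beaconStreams(cohort)[[key]], w$startTime,
                           cohort@layout, windowSec)
    w$rawLocation <- loc$rawLocation
    w$canonicalLocation <- loc$canonicalLocation
    w$room <- loc$room
    w$truthState <- gt$state
    w$truthLocomotion <- gt$locomotion
    w$truthPosture <- gt$posture
    w$truthLocation <- gt$location
    w$truthRoom <- gt$room
    perDay[[key]] <- w
  }
  win <- do.call(rbind, perDay)
  rownames(win) <- NULL
  if (is.null(model)) {
    tr <- if (is.null(trainDays)) win else win[win$day %in% trainDays, ,
                                               drop = FALSE]
    model <- trainHierarchicalClassifier(
      tr[, .FEATURE_NAMES, drop = FALSE],
      data.frame(locomotion = tr$truthLocomotion,
                 posture = ifelse(tr$truthLocomotion == "walking",
                                  NA_character_, tr$truthPosture)),
      seed = seed, cvFolds = 0L)
  }
  pred <- classifyWindows(model, win[, .FEATURE_NAMES, drop = FALSE],
                          win$mad, madThreshold)
  win$locomotion <- pred$locomotion
  win$motionState <- pred$motionState
  win$posture <- pred$posture
  win$state <- .stateFromPrediction(pred$locomotion, pred$posture)
  list(windows = win, model = model)
}

#' Run the full pipeline: simulate, process, localize, feature, compare
#'
#' Executes every stage in order under one seed: synthetic cohort
#' generation, signal processing and activity recognition, indoor
#' localization, inclusion/baseline selection and feature engineering, group
#' statistics, feature ranking and (when both outcome groups survive
#' inclusion) the cross-validated random-forest model on the top-ranked
#' feature. Outputs are written as CSV plus a provenance log; a fixed seed
#' reproduces every file byte-for-byte.
#'
#' @param config A pipeline configuration from [pipelineConfig()].
#' @param outDir Output directory (created if needed); `NULL` skips writing.
#' @return Invisible list: `features`, `stats`, `model`, `windows`,
#'   `provenance`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  validatePipelineConfig(config)
  cc <- cohortConfig(nCommunity = config$nCommunity,
                     nHospital = config$nHospital, seed = config$seed,
                     sampleRate = config$sampleRate)
  spec <- filterSpec(order = config$filterOrder, low = config$filterLow,
                     high = config$filterHigh,
                     sampleRate = config$sampleRate)
  cohort <- generateCohort(cc, days = config$days)
  proc <- processCohort(cohort, spec, config$windowSec, config$overlapSec,
                        config$madThreshold, seed = config$seed)
  ft <- buildFeatureTable(proc$windows, cohortMetadata(cohort),
                          strideSec = config$windowSec - config$overlapSec,
                          maxDay = config$maxBaselineDay,
                          minUptimeMin = config$minUptimeMin,
                          minTherapyMin = config$minTherapyMin)
  stats <- rankFeatures(compareGroups(ft))
  modelEval <- NULL
  if (nrow(ft) && length(unique(ft$outcome)) == 2L && nrow(stats)) {
    top <- stats$feature[which(!is.na(stats$p))[1L]]
    if (!is.na(top)) {
      x <- ft[, top, drop = FALSE]
      ok <- is.finite(x[[1L]])
      modelEval <- evaluateRf(x[ok, , drop = FALSE], ft$outcome[ok],
                              seed = config$seed)
      modelEval$feature <- top
    }
  }
  provenance <- list(seed = config$seed, config = unclass(config),
                     package = as.character(utils::packageVersion("rehabsense")),
                     nWindows = nrow(proc$windows),
                     included = nrow(ft),
                     excluded = attr(ft, "excluded"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(ft, file.path(outDir, "features.csv"))
    data.table::fwrite(stats, file.path(outDir, "stats.csv"))
    if (!is.null(modelEval))
      data.table::fwrite(cbind(feature = modelEval$feature,
                               modelEval$perFold),
                         file.path(outDir, "model.csv"))
    writePipelineConfig(config, file.path(outDir, "config.yaml"))
    provenance$configHash <-
      unname(tools::md5sum(file.path(outDir, "config.yaml")))
    yaml::write_yaml(provenance, file.path(outDir, "provenance.yaml"))
  }
  invisible(list(features = ft, stats = stats, model = modelEval,
                 windows = proc$windows, provenance = provenance))
}
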