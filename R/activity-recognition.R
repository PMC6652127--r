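#' @include signal-processing.R
NULL

.FEATURE_NAMES <- c("mean", "median", "variance", "skewness", "kurtosis",
                    "peakFrequency", "peakPower")

#' Extract the 7 window features
#'
#' Time-domain moments (mean, median, variance, skewness, kurtosis) of the
#' filtered window plus the frequency of the strongest one-sided spectral
#' component over (0, Nyquist] and its power. Zero-variance windows get
#' skewness and kurtosis 0 by convention so downstream classifiers accept
#' them.
#'
#' @param x Filtered magnitude window (numeric).
#' @param sampleRate Sampling rate in Hz.
#' @return Named numeric vector of the 7 features.
#' @examples
#' t <- seq(0, 10 - 1 / 16, by = 1 / 16)
#' extractWindowFeatures(sin(2 * pi * 2 * t), 16)[["peakFrequency"]]  # 2
#' @export
extractWindowFeatures <- function(x, sampleRate = 16) {
  m <- matrix(x, ncol = 1L)
  ft <- windowFeatureTable(m, sampleRate)[1L, ]
  stats::setNames(as.numeric(ft), names(ft))
}

#' Window features for a matrix of windows
#'
#' Column-wise version of [extractWindowFeatures()] for a
#' `samples x windows` matrix.
#'
#' @param mat Numeric matrix, one window per column.
#' @param sampleRate Sampling rate in Hz.
#' @return data.frame with the 7 feature columns, one row per window.
#' @export
windowFeatureTable <- function(mat, sampleRate = 16) {
  n <- nrow(mat)
  mu <- colMeans(mat)
  med <- apply(mat, 2L, stats::median)
  v <- apply(mat, 2L, stats::var)
  sk <- apply(mat, 2L, function(w)
    if (stats::sd(w) < 1e-12) 0 else e1071::skewness(w))
  ku <- apply(mat, 2L, function(w)
    if (stats::sd(w) < 1e-12) 0 else e1071::kurtosis(w))
  ## one-sided power spectrum over (0, Nyquist]
  P <- Mod(stats::mvfft(mat))^2 / n^2
  ks <- seq_len(floor(n / 2))          # skip DC
  f <- ks * sampleRate / n
  P1 <- P[ks + 1L, , drop = FALSE]
  peak <- apply(P1, 2L, which.max)
  data.frame(mean = mu, median = med, variance = v, skewness = sk,
             kurtosis = ku, peakFrequency = f[peak],
             peakPower = P1[cbind(peak, seq_len(ncol(mat)))])
}

## stratified k-fold assignment
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fitStage <- function(x, y, ntree) {
  randomForest::randomForest(x = x, y = factor(y), ntree = ntree)
}

.cvStage <- function(x, y, folds, ntree) {
  fold <- .stratifiedFolds(y, folds)
  pred <- character(length(y))
  for (k in seq_len(folds)) {
    hold <- fold == k
    fit <- .fitStage(x[!hold, , drop = FALSE], y[!hold], ntree)
    pred[hold] <- as.character(predict(fit, x[hold, , drop = FALSE]))
  }
  confusionStats(y, pred)
}

#' Train the hierarchical activity classifier
#'
#' Fits the two learned stages of the hierarchy on labeled windows: stage 1
#' (walking vs stationary) on all windows and stage 3 (stand/sit/lay) on the
#' stationary windows. The active/idle split (stage 2) needs no training --
#' it is the fixed MAD threshold. Per-stage k-fold cross-validated
#' precision/recall/F1 are recorded on the model.
#'
#' @param features data.frame of the 7 window features.
#' @param labels data.frame with `locomotion` (`walking`/`stationary`) and
#'   `posture` (`stand`/`sit`/`lay`, `NA` for walking windows).
#' @param algorithm Base learner id; `"randomForest"` is the default (and
#'   currently only) learner: shallow forests are robust on 7-feature
#'   tabular windows.
#' @param seed Training seed (fits and fold assignment are deterministic
#'   given it).
#' @param cvFolds Folds for the recorded cross-validation (0 skips it).
#' @param ntree Trees per forest.
#' @return A [HierarchicalModel-class].
#' @export
trainHierarchicalClassifier <- function(features, labels,
                                        algorithm = "randomForest",
                                        seed = 1L, cvFolds = 10L,
                                        ntree = 150L) {
  if (algorithm != "randomForest")
    stop("unknown algorithm id: ", algorithm)
  stopifnot(nrow(features) == nrow(labels))
  x <- features[, .FEATURE_NAMES, drop = FALSE]
  loco <- as.character(labels$locomotion)
  if (length(unique(loco)) < 2L)
    stop("stage 1 (walking vs stationary) requires both classes in labels")
  stat <- loco == "stationary"
  post <- as.character(labels$posture[stat])
  if (length(unique(post[!is.na(post)])) < 2L)
    stop("stage 3 (posture) requires >= 2 posture classes in labels")
  set.seed(seed)
  stage1 <- .fitStage(x, loco, ntree)
  x3 <- x[stat, , drop = FALSE][!is.na(post), , drop = FALSE]
  stage3 <- .fitStage(x3, post[!is.na(post)], ntree)
  cv <- list()
  if (cvFolds >= 2L) {
    cv$locomotion <- .cvStage(x, loco, cvFolds, ntree)
    cv$posture <- .cvStage(x3, post[!is.na(post)], cvFolds, ntree)
  }
  new("HierarchicalModel", stage1 = stage1, stage3 = stage3,
      algorithm = algorithm, seed = as.integer(seed),
      featureNames = .FEATURE_NAMES, cvStats = cv)
}

#' Apply the activity hierarchy to windows
#'
#' Stage 1 assigns walking vs stationary from the learned model; stationary
#' windows get their active/idle state from the MAD threshold and a posture
#' from stage 3. Walking windows carry no posture and always count as active
#' downstream.
#'
#' @param model A fitted [HierarchicalModel-class].
#' @param features data.frame of the 7 window features (one row per window).
#' @param mad Per-window MAD in m/s^2.
#' @param madThreshold Active/idle threshold in m/s^2.
#' @return data.frame with `locomotion`, `motionState`, `posture`.
#' @export
classifyWindows <- function(model, features, mad, madThreshold = 0.02) {
  if (!is(model, "HierarchicalModel") || is.null(model@stage1))
    stop("model must be a fitted HierarchicalModel")
  x <- features[, model@featureNames, drop = FALSE]
  stopifnot(nrow(x) == length(mad))
  loco <- as.character(predict(model@stage1, x))
  posture <- rep(NA_character_, nrow(x))
  motion <- rep("active", nrow(x))        # walking embodies active status
  stat <- loco == "stationary"
  if (any(stat)) {
    posture[stat] <- as.character(predict(model@stage3,
                                          x[stat, , drop = FALSE]))
    motion[stat] <- classifyMotionState(mad[stat], madThreshold)
  }
  data.frame(locomotion = loco, motionState = motion, posture = posture)
}

#' Precision/recall/F1 from paired labels
#'
#' Per-class precision, recall and F1 from a confusion of true vs predicted
#' labels, plus overall accuracy and macro / support-weighted averages.
#'
#' @param true,pred Equal-length label vectors.
#' @return List with `byClass` (data.frame), `accuracy`, `macroF1`,
#'   `weightedF1`, and the confusion `table`.
#' @export
confusionStats <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  stopifnot(length(true) == length(pred))
  classes <- sort(union(true, pred))
  tab <- table(factor(true, classes), factor(pred, classes))
  tp <- diag(tab)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), NA_real_)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), NA_real_)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  support <- rowSums(tab)
  byClass <- data.frame(class = classes, precision = as.numeric(prec),
                        recall = as.numeric(rec), f1 = as.numeric(f1),
                        support = as.numeric(support))
  w <- support / sum(support)
  list(byClass = byClass, accuracy = sum(tp) / sum(tab),
       macroF1 = mean(f1, na.rm = TRUE),
       weightedF1 = sum(w * ifelse(is.na(f1), 0, f1)),
       table = tab)
}

#' Majority ground-truth labels for analysis windows
#'
#' For each window start, the schedule segment with the largest time overlap
#' supplies the ground-truth posture, motion, location and room -- the
#' reference the recognition and localization stages are scored against on
#' synthetic data.
#'
#' @param schedule A [ProtocolSchedule-class].
#' @param windowStarts Window start times (s).
#' @param windowSec Window duration (s).
#' @return data.frame with `startTime`, `posture`, `motion`, `location`,
#'   `room`, `locomotion`, `state` (walking/standing/sitting/laying).
#' @export
windowGroundTruth <- function(schedule, windowStarts, windowSec = 10) {
  seg <- segments(schedule)
  nw <- length(windowStarts)
  if (!nw)
    return(data.frame(startTime = numeric(0), posture = character(0),
                      motion = character(0), location = character(0),
                      room = character(0), locomotion = character(0),
                      state = character(0)))
  we <- windowStarts + windowSec
  ## overlap of each window with each segment
  ov <- pmax(outer(we, seg$end, pmin) - outer(windowStarts, seg$start, pmax),
             0)
  best <- apply(ov, 1L, which.max)
  posture <- seg$posture[best]
  motion <- seg$motion[best]
  loco <- ifelse(motion == "walk", "walking", "stationary")
  state <- ifelse(motion == "walk", "walking",
                  c(stand = "standing", sit = "sitting",
                    lay = "laying")[posture])
  data.frame(startTime = windowStarts, posture = posture, motion = motion,
             location = seg$location[best],
             room = .locationRoom(seg$location[best]), locomotion = loco,
             state = as.character(state))
}
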