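#' @include feature-engine.R
NULL

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and the chi-square p-value
#' approximation, as used for the quantitative group comparisons.
#'
#' @param valuesByGroup Named list of numeric vectors, one per group (>= 2
#'   groups, each non-empty).
#' @return List with `H` and `p`.
#' @examples
#' kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskalWallis <- function(valuesByGroup) {
  if (length(valuesByGroup) < 2L)
    stop("need at least 2 groups")
  if (any(!vapply(valuesByGroup, length, 1L)))
    stop("every group must be non-empty")
  x <- unlist(valuesByGroup, use.names = FALSE)
  g <- factor(rep(names(valuesByGroup) %||% seq_along(valuesByGroup),
                  vapply(valuesByGroup, length, 1L)))
  if (length(unique(x)) == 1L)      # all observations tied: no evidence
    return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square test on a contingency table
#'
#' Expected counts from the margins, no continuity correction by default
#' (the convention used for the categorical demographic comparisons); a
#' Yates-corrected variant is available via `correct = TRUE`.
#'
#' @param tab 2-D non-negative integer matrix/table.
#' @param correct Apply the continuity correction.
#' @return List with `statistic` and `p`.
#' @examples
#' chiSquareTest(matrix(c(10, 0, 0, 10), 2))$statistic  # 20
#' @export
chiSquareTest <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (length(dim(tab)) != 2L) stop("tab must be 2-dimensional")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("tab must contain non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference pooled with the unweighted average of the
#' two group variances, `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)` -- the pooling
#' convention that reproduces this study population's published effect
#' sizes from the printed group means and SDs.
#'
#' @param mean1,sd1 First group (community, by convention).
#' @param mean2,sd2 Second group (hospital).
#' @return Signed d; positive when the first group's mean is larger.
#' @examples
#' round(cohensD(44.22, 7.94, 32.68, 7.30), 2)  # 1.51
#' @export
cohensD <- function(mean1, sd1, mean2, sd2) {
  if (any(sd1 < 0) || any(sd2 < 0)) stop("sds must be >= 0")
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (any(pooled == 0)) stop("both group sds are zero; d is undefined")
  (mean1 - mean2) / pooled
}

#' Cohen's d from raw samples
#'
#' Convenience wrapper computing the group means/SDs and delegating to
#' [cohensD()].
#'
#' @param x1,x2 Numeric samples for the two groups.
#' @return Signed d.
#' @export
cohensDFromSamples <- function(x1, x2) {
  cohensD(mean(x1), stats::sd(x1), mean(x2), stats::sd(x2))
}

#' Spearman correlation matrix of a feature table
#'
#' Pairwise-complete Spearman rho over the numeric columns; symmetric with
#' unit diagonal and invariant under monotone transforms of any column.
#' Constant columns yield `NA` for their pairs.
#'
#' @param features data.frame (>= 3 rows); non-numeric columns are dropped.
#' @return Numeric matrix of rho values.
#' @export
spearmanMatrix <- function(features) {
  num <- features[vapply(features, is.numeric, TRUE)]
  if (nrow(num) < 3L) stop("need at least 3 rows")
  rho <- suppressWarnings(
    stats::cor(num, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- ifelse(vapply(num, function(c)
    stats::sd(c, na.rm = TRUE) > 0, TRUE), 1, NA_real_)
  rho
}

#' Compare every feature between outcome groups
#'
#' Per-feature group summaries (mean, SD, n on the available values),
#' Kruskal-Wallis p-value and Cohen's d (signed community - hospital), plus
#' the availability counts mirrored from the per-feature frequency columns.
#'
#' @param featureTable data.frame from [buildFeatureTable()] (needs an
#'   `outcome` column; bookkeeping columns are skipped).
#' @param skip Columns to exclude from comparison.
#' @return data.frame: `feature, mean_C, sd_C, n_C, mean_H, sd_H, n_H, p, d`.
#' @export
compareGroups <- function(featureTable,
                          skip = c("patientId", "outcome", "baselineDay")) {
  stopifnot("outcome" %in% names(featureTable))
  g <- featureTable$outcome
  cols <- setdiff(names(featureTable)[vapply(featureTable, is.numeric,
                                             TRUE)], skip)
  rows <- lapply(cols, function(f) {
    xC <- featureTable[[f]][g == "community"]
    xH <- featureTable[[f]][g == "hospital"]
    xC <- xC[is.finite(xC)]; xH <- xH[is.finite(xH)]
    p <- d <- NA_real_
    if (length(xC) >= 2L && length(xH) >= 2L) {
      if (stats::sd(c(xC, xH)) > 0)
        p <- kruskalWallis(list(community = xC, hospital = xH))$p
      if (stats::sd(xC) > 0 || stats::sd(xH) > 0)
        d <- cohensDFromSamples(xC, xH)
    }
    data.frame(feature = f,
               mean_C = if (length(xC)) mean(xC) else NA_real_,
               sd_C = if (length(xC) > 1) stats::sd(xC) else NA_real_,
               n_C = length(xC),
               mean_H = if (length(xH)) mean(xH) else NA_real_,
               sd_H = if (length(xH) > 1) stats::sd(xH) else NA_real_,
               n_H = length(xH), p = p, d = d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank features by discriminatory strength
#'
#' Sorted by p-value ascending; ties break to the larger absolute effect
#' size.
#'
#' @param comparisons data.frame with `p` and `d` columns (e.g. from
#'   [compareGroups()]).
#' @return The comparisons reordered.
#' @export
rankFeatures <- function(comparisons) {
  if (!nrow(comparisons)) return(comparisons)
  out <- comparisons[order(comparisons$p, -abs(comparisons$d)), ,
                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validated random-forest outcome model
#'
#' Stratified k-fold (default 3) cross-validation of a shallow random
#' forest (depth capped at `maxDepth` via the maximum number of terminal
#' nodes, balanced class weights, fixed `seed`) predicting the hospital
#' outcome from a feature subset. Sensitivity is the recall of the hospital
#' (positive, minority) class only; specificity the true-negative rate on
#' community; AUC from the out-of-fold class probabilities. Folds lacking a
#' hospital case are flagged, not dropped.
#'
#' @param features data.frame of predictor columns.
#' @param outcome Character/factor vector, `"community"`/`"hospital"`.
#' @param folds Number of CV folds.
#' @param maxDepth Maximum tree depth (terminal nodes capped at
#'   `2^maxDepth`).
#' @param seed Random state controlling folds and fits.
#' @param ntree Trees per forest.
#' @return List with `perFold` (data.frame: sensitivity, specificity,
#'   accuracy in %, auc, flagged) and `summary` (mean and SD across folds).
#' @export
evaluateRf <- function(features, outcome, folds = 3L, maxDepth = 2L,
                       seed = 40L, ntree = 500L) {
  features <- as.data.frame(features)
  y <- factor(as.character(outcome), levels = c("community", "hospital"))
  if (any(is.na(y))) stop("outcome must be community/hospital")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  set.seed(seed)
  fold <- .stratifiedFolds(as.character(y), folds)
  classwt <- c(community = 1 / sum(y == "community"),
               hospital = 1 / sum(y == "hospital"))
  classwt <- classwt / sum(classwt)
  per <- vector("list", folds)
  for (k in seq_len(folds)) {
    hold <- fold == k
    fit <- randomForest::randomForest(
      x = features[!hold, , drop = FALSE], y = y[!hold], ntree = ntree,
      maxnodes = 2L^maxDepth, classwt = classwt)
    pred <- predict(fit, features[hold, , drop = FALSE])
    prob <- predict(fit, features[hold, , drop = FALSE],
                    type = "prob")[, "hospital"]
    truth <- y[hold]
    tp <- sum(truth == "hospital" & pred == "hospital")
    fn <- sum(truth == "hospital" & pred == "community")
    tn <- sum(truth == "community" & pred == "community")
    fp <- sum(truth == "community" & pred == "hospital")
    flagged <- sum(truth == "hospital") == 0L
    auc <- if (flagged) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob,
                                     levels = c("community", "hospital"),
                                     direction = "<", quiet = TRUE)))
    per[[k]] <- data.frame(
      fold = k,
      sensitivity = if (flagged) NA_real_ else 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      accuracy = 100 * (tp + tn) / length(truth),
      auc = auc, flagged = flagged)
  }
  perFold <- do.call(rbind, per)
  sm <- function(v) c(mean = mean(v, na.rm = TRUE),
                      sd = stats::sd(v, na.rm = TRUE))
  list(perFold = perFold,
       summary = data.frame(
         metric = c("sensitivity", "specificity", "accuracy", "auc"),
         mean = c(sm(perFold$sensitivity)[1], sm(perFold$specificity)[1],
                  sm(perFold$accuracy)[1], sm(perFold$auc)[1]),
         sd = c(sm(perFold$sensitivity)[2], sm(perFold$specificity)[2],
                sm(perFold$accuracy)[2], sm(perFold$auc)[2])),
       hyperparameters = list(maxDepth = maxDepth, seed = seed,
                              classWeight = "balanced", folds = folds))
}
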