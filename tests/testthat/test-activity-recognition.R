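# windows with all three postures + walking, simulated once per file
recognitionFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- shortDayConfig(dayEnd = 11 * 3600)  # 2-h day
    segs <- list(); t <- 9 * 3600
    set.seed(42)
    specs <- data.frame(
      posture = c("lay", "sit", "stand", "stand", "lay", "sit", "stand"),
      motion = c("idle", "active", "active", "walk", "active", "idle",
                 "idle"),
      location = c("resident_bed1", "chair", "toilet", "toilet",
                   "resident_bed2", "chair", "resident_bed1"))
    for (i in seq_len(nrow(specs))) {
      dur <- if (specs$motion[i] == "walk") 120 else 17 * 60
      segs[[i]] <- oneSegment(dur, location = specs$location[i],
                              posture = specs$posture[i],
                              motion = specs$motion[i], start = t)
      t <- t + dur
    }
    sch <- manualSchedule(do.call(rbind, segs),
                          params = list(residentIntensity = 43))
    w <- processAccelStream(simulateAccelerometer(sch, cfg))
    gt <- windowGroundTruth(sch, w$startTime)
    cache <<- list(windows = w, truth = gt)
    cache
  }
})

test_that("the 7 window features behave on canonical inputs", {
  z <- extractWindowFeatures(rep(0, 160))
  expect_equal(unname(z[c("mean", "variance", "skewness", "kurtosis")]),
               c(0, 0, 0, 0))
  s2 <- extractWindowFeatures(sineSeries(2, 160), 16)
  expect_equal(s2[["peakFrequency"]], 2)
  # homogeneity under scaling
  x <- rnorm(160)
  f1 <- extractWindowFeatures(x)
  f3 <- extractWindowFeatures(3 * x)
  expect_equal(f3[["variance"]], 9 * f1[["variance"]])
  expect_equal(f3[["median"]], 3 * f1[["median"]])
  expect_equal(f3[["skewness"]], f1[["skewness"]])
})

test_that("hierarchy trains to high CV scores on separable labels", {
  fx <- recognitionFixture()
  labels <- data.frame(
    locomotion = fx$truth$locomotion,
    posture = ifelse(fx$truth$locomotion == "walking", NA_character_,
                     fx$truth$posture))
  model <- trainHierarchicalClassifier(fx$windows, labels, seed = 9,
                                       cvFolds = 10, ntree = 100)
  expect_gte(model@cvStats$locomotion$weightedF1, 0.95)
  post <- model@cvStats$posture$byClass
  expect_true(all(post$recall >= 0.90))

  # single-class stages are rejected by name
  allWalk <- data.frame(locomotion = rep("walking", 10),
                        posture = NA_character_)
  expect_error(trainHierarchicalClassifier(fx$windows[1:10, ], allWalk),
               "stage 1")
  oneP <- data.frame(locomotion = rep(c("walking", "stationary"), c(2, 8)),
                     posture = rep(c(NA_character_, "lay"), c(2, 8)))
  expect_error(trainHierarchicalClassifier(fx$windows[1:10, ], oneP),
               "stage 3")
})

test_that("classification respects the hierarchy and the MAD threshold", {
  fx <- recognitionFixture()
  labels <- data.frame(
    locomotion = fx$truth$locomotion,
    posture = ifelse(fx$truth$locomotion == "walking", NA_character_,
                     fx$truth$posture))
  model <- trainHierarchicalClassifier(fx$windows, labels, seed = 9,
                                       cvFolds = 0, ntree = 100)
  pred <- classifyWindows(model, fx$windows, fx$windows$mad)

  # walking never carries a posture; stationary always does
  expect_true(all(is.na(pred$posture[pred$locomotion == "walking"])))
  expect_true(all(!is.na(pred$posture[pred$locomotion == "stationary"])))
  # walking embodies active status
  expect_true(all(pred$motionState[pred$locomotion == "walking"] ==
                    "active"))
  # stationary windows follow the threshold exactly
  stat <- pred$locomotion == "stationary"
  expect_equal(pred$motionState[stat],
               classifyMotionState(fx$windows$mad[stat]))
  # near-zero MAD stationary window: idle with some posture
  low <- which(stat & fx$windows$mad < 0.02)[1]
  expect_equal(pred$motionState[low], "idle")
  expect_true(pred$posture[low] %in% c("stand", "sit", "lay"))

  # determinism and ground-truth agreement on the training day
  pred2 <- classifyWindows(model, fx$windows, fx$windows$mad)
  expect_identical(pred, pred2)
  agree <- mean(pred$locomotion == fx$truth$locomotion)
  expect_gte(agree, 0.9)
  expect_error(classifyWindows(new("HierarchicalModel", stage1 = NULL),
                               fx$windows, fx$windows$mad), "fitted")
})

test_that("confusion-derived metrics equal hand-computed values", {
  # toy 3-class problem with a known confusion structure:
  #          pred a  b  c
  # true a:       8  1  1   (10)
  # true b:       2  6  2   (10)
  # true c:       0  0  5   (5)
  true <- rep(c("a", "b", "c"), c(10, 10, 5))
  pred <- c(rep("a", 8), "b", "c",
            "a", "a", rep("b", 6), "c", "c",
            rep("c", 5))
  cs <- confusionStats(true, pred)
  by <- cs$byClass
  expect_equal(by$precision[by$class == "a"], 8 / 10)
  expect_equal(by$recall[by$class == "a"], 8 / 10)
  expect_equal(by$precision[by$class == "b"], 6 / 7)
  expect_equal(by$recall[by$class == "b"], 6 / 10)
  expect_equal(by$precision[by$class == "c"], 5 / 8)
  expect_equal(by$recall[by$class == "c"], 5 / 5)
  expect_equal(by$f1[by$class == "b"],
               2 * (6 / 7) * (6 / 10) / (6 / 7 + 6 / 10))
  expect_equal(cs$accuracy, 19 / 25)
})

test_that("ground-truth labels follow the majority-overlap rule", {
  seg <- rbind(oneSegment(100, posture = "lay", motion = "idle"),
               oneSegment(100, posture = "stand", motion = "walk",
                          location = "toilet", start = 9 * 3600 + 100))
  sch <- manualSchedule(seg)
  # window straddling the boundary: 6 s in lay, 4 s in walk -> lay
  gt <- windowGroundTruth(sch, 9 * 3600 + c(0, 94, 96, 150), windowSec = 10)
  expect_equal(gt$state, c("laying", "laying", "walking", "walking"))
  expect_equal(gt$locomotion, c("stationary", "stationary", "walking",
                                "walking"))
  expect_equal(gt$room, rep("resident", 4))
})
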