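# synthetic window table with known composition (no waveform synthesis)
windowTableFixture <- function(n = 400, seed = 5) {
  set.seed(seed)
  state <- sample(c("walking", "standing", "sitting", "laying"), n, TRUE,
                  prob = c(0.01, 0.44, 0.09, 0.46))
  motion <- ifelse(state == "walking", "active",
                   ifelse(runif(n) < 0.13, "active", "idle"))
  loc <- sample(c("resident_bed", "bathroom", "chair", "bike", "unknown"),
                n, TRUE, prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
  room <- ifelse(loc == "unknown", "unknown",
                 ifelse(loc == "bike", "therapy", "resident"))
  data.frame(patientId = "P001", day = 1L,
             madCm = ifelse(motion == "active", runif(n, 2, 80),
                            runif(n, 0, 1.9)),
             state = state, motionState = motion, canonicalLocation = loc,
             room = room)
}

test_that("uptime accumulates worn minutes", {
  expect_equal(computeUptime(data.frame(start = 9 * 3600, end = 18 * 3600)),
               540)
  expect_equal(computeUptime(data.frame(start = c(0, 10000),
                                        end = c(7200, 19000))), 270)
  expect_equal(computeUptime(data.frame(start = numeric(0),
                                        end = numeric(0))), 0)
})

test_that("baseline day selection enforces both inclusion rules", {
  sel <- selectBaselineDay(data.frame(day = 1:2, uptimeMin = c(239, 300),
                                      therapyMin = c(20, 20)))
  expect_equal(sel$chosenDay, 2L)
  sel2 <- selectBaselineDay(data.frame(day = 1:2, uptimeMin = c(300, 500),
                                       therapyMin = c(16, 60)))
  expect_equal(sel2$chosenDay, 1L)  # earliest qualifying wins
  sel3 <- selectBaselineDay(data.frame(day = 1:3, uptimeMin = rep(200, 3),
                                       therapyMin = rep(10, 3)))
  expect_true(sel3$excluded)
  # a qualifying day outside the first 3 days does not rescue the patient
  sel4 <- selectBaselineDay(data.frame(day = c(1, 4),
                                       uptimeMin = c(100, 500),
                                       therapyMin = c(5, 60)))
  expect_true(sel4$excluded)
  expect_error(selectBaselineDay(data.frame(day = integer(0),
                                            uptimeMin = numeric(0),
                                            therapyMin = numeric(0))),
               "candidate")
})

test_that("normalized feature primitives satisfy their closed forms", {
  expect_equal(timePercent(270, 540), 50)
  expect_equal(timePercent(0, 540), 0)
  expect_equal(timePercent(540, 540), 100)
  expect_error(timePercent(10, 0), "uptime")

  expect_equal(windowEnergy(0, 0.15), 0)
  expect_equal(windowEnergy(10, 0.15) * 2, windowEnergy(20, 0.15))
  expect_equal(windowEnergy(c(5, 5), 0.15), rep(0.75, 2))

  expect_equal(energyIntensity(120, 60), 2)
  expect_true(is.na(energyIntensity(0, 0)))   # absent, not zero
  expect_equal(energyIntensity(0, 10), 0)

  expect_equal(energyPercent(c(25, 25, 25, 25), 100), rep(25, 4))
  expect_equal(energyPercent(40, 40), 100)
  expect_error(energyPercent(1, 0), "total")

  expect_equal(intensityBand(c(59, 90, 120)),
               c("light", "moderate_to_vigorous", "moderate_to_vigorous"))
  expect_equal(intensityBand(89, cutoff = 85), "moderate_to_vigorous")
  expect_error(intensityBand(-1), ">= 0")
})

test_that("per-day features close the time and energy accounting", {
  w <- windowTableFixture()
  ft <- patientDayFeatures(w, strideSec = 9, uptimeMin = 540)
  # exclusive state partition sums to exactly 100
  tsum <- ft$time_pct_walking + ft$time_pct_standing + ft$time_pct_sitting +
    ft$time_pct_laying
  expect_equal(tsum, 100, tolerance = 1e-12)
  esum <- ft$epct_walking + ft$epct_standing + ft$epct_sitting +
    ft$epct_laying
  expect_equal(esum, 100, tolerance = 1e-12)
  # energy conservation: states == total == locations + unknown, exactly
  eStates <- ft$e_walking + ft$e_standing + ft$e_sitting + ft$e_laying
  eLocs <- ft$e_loc_resident_bed + ft$e_loc_bathroom + ft$e_loc_chair +
    ft$e_loc_bike + ft$e_unknown
  expect_equal(eStates, ft$total_energy, tolerance = 1e-12)
  expect_equal(eLocs, ft$total_energy, tolerance = 1e-12)
  expect_equal(ft$e_resident_room + ft$e_therapy_room + ft$e_unknown,
               ft$total_energy, tolerance = 1e-12)

  # ratio identity: therapy/resident intensity from intensities vs raw sums
  r1 <- ft$ei_therapy_room / ft$ei_resident_room
  minT <- sum(w$room == "therapy") * 9 / 60
  minR <- sum(w$room == "resident") * 9 / 60
  eT <- sum(w$madCm[w$room == "therapy"]) * 9 / 60
  eR <- sum(w$madCm[w$room == "resident"]) * 9 / 60
  expect_equal(r1, (eT / minT) / (eR / minR), tolerance = 1e-9)

  # absent locations: NA intensity, zero time
  ft2 <- patientDayFeatures(w, strideSec = 9,
                            locations = c("resident_bed", "wall"))
  expect_true(is.na(ft2$ei_loc_wall))
  expect_equal(ft2$time_pct_loc_wall, 0)
})

test_that("feature table applies inclusion and is reproducible", {
  w1 <- windowTableFixture(seed = 5)
  w2 <- transform(windowTableFixture(n = 300, seed = 6), patientId = "P002")
  w3 <- transform(windowTableFixture(n = 50, seed = 7), patientId = "P003")
  windows <- rbind(w1, w2, w3)
  # P003 fails the uptime rule; P001/P002 qualify (therapy via bike windows)
  md <- data.frame(patientId = c("P001", "P002", "P003"), day = 1L,
                   outcome = c("community", "community", "hospital"),
                   uptimeMin = c(300, 280, 100))
  ft <- buildFeatureTable(windows, md, minTherapyMin = 1)
  expect_equal(ft$patientId, c("P001", "P002"))
  expect_equal(attr(ft, "excluded"), "P003")
  ftb <- buildFeatureTable(windows, md, minTherapyMin = 1)
  attr(ft, "excluded") <- attr(ftb, "excluded") <- NULL
  expect_identical(ft, ftb)
  # one row per included patient and shared location columns
  expect_true(all(c("time_pct_standing", "ei_resident_room",
                    "epct_active", "total_ei") %in% names(ft)))
})

test_that("standing dominates the community energy budget in simulation", {
  cfg <- shortDayConfig(dayEnd = 12 * 3600)
  set.seed(23)
  params <- drawPatientParameters(cfg, "community")
  sch <- makeProtocolSchedule(cfg, "community", params = params)
  w <- processAccelStream(simulateAccelerometer(sch, cfg))
  gt <- windowGroundTruth(sch, w$startTime)
  w$state <- gt$state
  w$motionState <- ifelse(gt$motion == "idle", "idle", "active")
  w$canonicalLocation <- aggregateLocation(gt$location)
  w$room <- gt$room
  ft <- patientDayFeatures(w, strideSec = 9)
  eps <- unlist(ft[paste0("epct_", c("walking", "standing", "sitting",
                                     "laying"))])
  expect_equal(names(which.max(eps)), "epct_standing")
})
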