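test_that("full-wear protocol day spans 540 worn minutes", {
  set.seed(4)
  cfg <- cohortConfig(dropoutProb = 0, gapProb = 0)
  sch <- makeProtocolSchedule(cfg, "community")
  expect_equal(computeUptime(wearMask(sch)), 540)
  seg <- segments(sch)
  expect_equal(min(seg$start), 9 * 3600)
  expect_equal(max(seg$end), 18 * 3600)
})

test_that("schedules honour group dwell parameters and protocol structure", {
  cfg <- cohortConfig(dropoutProb = 0, gapProb = 0)
  # hospital laying-time parameter centres on the group mean (~61% of uptime)
  expect_equal(defaultGroupEffects()$layingTimePct[["hospital"]], 60.99)
  set.seed(11)
  lay <- replicate(300, drawPatientParameters(cfg, "hospital")$layPct)
  expect_equal(mean(lay), 60.99, tolerance = 0.03)

  # exactly one contiguous therapy block near an hour
  set.seed(12)
  sch <- makeProtocolSchedule(cfg, "community")
  seg <- segments(sch)
  th <- seg$location %in%
    c("therapy_bed1", "therapy_bed2", "bike", "small_table", "resband",
      "wall1")
  runs <- rle(th)
  expect_equal(sum(runs$values), 1L)
  expect_gte(sum(seg$end[th] - seg$start[th]) / 60, 30)
  expect_lte(sum(seg$end[th] - seg$start[th]) / 60, 90)

  # walking only while standing; segments ordered and non-overlapping
  expect_true(all(seg$posture[seg$motion == "walk"] == "stand"))
  expect_true(all(diff(seg$start) > 0))
  expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)] - 1e-9))

  expect_error(makeProtocolSchedule(cfg, "outpatient"), "outcome")
})

test_that("identical seeds reproduce identical schedules and streams", {
  cfg <- shortDayConfig()
  set.seed(99); a <- makeProtocolSchedule(cfg, "community")
  set.seed(99); b <- makeProtocolSchedule(cfg, "community")
  expect_identical(segments(a), segments(b))
  expect_identical(wearMask(a), wearMask(b))
  set.seed(5); sa <- simulateAccelerometer(a, cfg)
  set.seed(5); sb <- simulateAccelerometer(b, cfg)
  expect_identical(as.data.frame(sa), as.data.frame(sb))
  lay <- defaultBeaconLayout()
  set.seed(6); ra <- simulateRssi(a, lay, cfg)
  set.seed(6); rb <- simulateRssi(b, lay, cfg)
  expect_identical(beaconEvents(ra), beaconEvents(rb))
})

test_that("accelerometer synthesis: gravity, thresholds, clipping, wear", {
  # static segment with zero noise: SM is exactly 1 g at every sample
  cfg0 <- shortDayConfig(sensorNoise = 0, microMovementScale = 0)
  sch <- manualSchedule(oneSegment(300))
  set.seed(1)
  st <- simulateAccelerometer(sch, cfg0)
  sm <- computeSignalMagnitude(st@ax, st@ay, st@az)
  expect_equal(sm, rep(1, length(st)), tolerance = 1e-12)

  # idle-lay windows sit below, active windows above, the 0.02 m/s^2 MAD
  cfg <- shortDayConfig()
  set.seed(2)
  idle <- processAccelStream(simulateAccelerometer(
    manualSchedule(oneSegment(600, posture = "lay", motion = "idle")), cfg))
  expect_true(all(idle$mad < 0.02))
  set.seed(3)
  act <- processAccelStream(simulateAccelerometer(
    manualSchedule(oneSegment(600, posture = "sit", motion = "active",
                              location = "chair")), cfg))
  expect_true(all(act$mad >= 0.02))

  # walking: spectral peak of the filtered magnitude in the cadence band
  set.seed(4)
  walk <- processAccelStream(simulateAccelerometer(
    manualSchedule(oneSegment(600, posture = "stand", motion = "walk",
                              location = "toilet")), cfg))
  expect_true(all(walk$peakFrequency >= 1.4 & walk$peakFrequency <= 2.6))

  # clipping and wear-mask discipline
  set.seed(5)
  full <- simulateAccelerometer(makeProtocolSchedule(cfg, "community"), cfg)
  expect_lte(max(abs(c(full@ax, full@ay, full@az))), 2)
})

test_that("no accelerometer samples fall outside the wear mask", {
  cfg <- cohortConfig(dropoutProb = 1, gapProb = 0)
  set.seed(21)
  sch <- makeProtocolSchedule(cfg, "community")
  st <- simulateAccelerometer(sch, cfg)
  wm <- wearMask(sch)
  inWear <- rep(FALSE, length(st@time))
  for (i in seq_len(nrow(wm)))
    inWear <- inWear | (st@time >= wm$start[i] & st@time <= wm$end[i])
  expect_true(all(inWear))
  # empty schedule -> empty stream
  empty <- new("ProtocolSchedule", patientId = "PX", dayIndex = 1L,
               outcome = "community",
               segments = data.frame(start = numeric(0), end = numeric(0),
                                     location = character(0),
                                     posture = character(0),
                                     motion = character(0)),
               wearMask = data.frame(start = numeric(0), end = numeric(0)),
               params = list())
  expect_equal(length(simulateAccelerometer(empty, cfg)), 0L)
})

test_that("RSSI synthesis follows the calibrated path-loss model", {
  cfg <- shortDayConfig(rssiNoiseSd = 0)
  # anchor: 1 ft line-of-sight is -66 dBm exactly
  expect_equal(rssiAtDistance(0.3048, cfg), -66)
  expect_lt(rssiAtDistance(3, cfg), rssiAtDistance(1, cfg))

  # occupied location's beacon has the highest mean RSSI in each segment
  lay <- defaultBeaconLayout()
  sch <- manualSchedule(rbind(
    oneSegment(120, location = "resident_bed1"),
    oneSegment(120, location = "toilet", posture = "stand",
               motion = "active", start = 9 * 3600 + 120)))
  set.seed(8)
  ev <- beaconEvents(simulateRssi(sch, lay, cfg))
  for (i in 1:2) {
    seg <- segments(sch)[i, ]
    sub <- ev[ev$time >= seg$start & ev$time < seg$end, ]
    mu <- tapply(sub$rssi, sub$beaconId, mean)
    expect_equal(names(which.max(mu)), paste0("b_", seg$location))
  }
  # event times within wear, advertisement cadence per beacon
  b1 <- ev$time[ev$beaconId == "b_bike"]
  expect_equal(unique(round(diff(b1), 9)), 0.25)

  expect_error(cohortConfig(advertInterval = 0), "advertInterval")
  bad <- manualSchedule(oneSegment(60, location = "garden"))
  expect_error(simulateRssi(bad, lay, cfg), "garden")
})

test_that("cohort generation: counts, candidate days, programmed effects", {
  cfg <- cohortConfig(nCommunity = 145L, nHospital = 9L, seed = 7L)
  coh <- generateCohort(cfg, days = 3, simulateStreams = FALSE)
  md <- cohortMetadata(coh)
  expect_equal(length(unique(md$patientId)), 154L)
  expect_equal(nrow(md), 154L * 3L)
  expect_equal(sum(md$outcome == "hospital") / 3L, 9L)

  expect_warning(empty <- generateCohort(cohortConfig(nCommunity = 0L,
                                                      nHospital = 0L)),
                 "empty cohort")
  expect_equal(nrow(cohortMetadata(empty)), 0L)

  # cohort draws recover the programmed resident-room intensity effect
  # (d = 1.25); at n_H = 9 a single replicate carries sd(d) ~ 0.35, so the
  # centre of a small Monte-Carlo sample is checked
  set.seed(31)
  ds <- replicate(25, {
    pars <- drawCohortParameters(cfg)
    cohensDFromSamples(
      pars$residentIntensity[pars$outcome == "community"],
      pars$residentIntensity[pars$outcome == "hospital"])
  })
  expect_lt(abs(median(ds) - 1.25), 0.2)
})

test_that("walking occupies a negligible share of a community day", {
  cfg <- cohortConfig(dropoutProb = 0, gapProb = 0)
  set.seed(17)
  frac <- replicate(20, {
    seg <- segments(makeProtocolSchedule(cfg, "community"))
    sum((seg$end - seg$start)[seg$motion == "walk"]) /
      sum(seg$end - seg$start)
  })
  expect_lt(mean(frac), 0.01)
})
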