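#' @include AllClasses.R
NULL

## Location vocabulary used by the default layout and schedule generator.
.RESIDENT_LOCS <- c("resident_bed1", "resident_bed2", "toilet", "chair")
.THERAPY_LOCS <- c("therapy_bed1", "therapy_bed2", "bike", "small_table",
                   "resband", "wall1")

## Posture signatures: unit gravity directions (wrist convention: the
## dominant axis rotates between standing and laying), micro-movement idle
## amplitudes (m/s^2) and posture-specific tremor/movement frequency bands
## (Hz) inside the 0.5-8 Hz band of interest. Walking cadence occupies
## 1.5-2.5 Hz.
.POSTURE_GRAVITY <- list(
  stand = c(0.93, 0.26, 0.26),
  sit = c(0.50, 0.71, 0.50),
  lay = c(0.12, 0.12, 0.99))
.IDLE_AMP <- c(lay = 0.004, sit = 0.012, stand = 0.020)
## active micro-movement scales with posture: upright activity is the most
## vigorous, movement while laying the least
.ACTIVE_POSTURE_FACTOR <- c(lay = 0.3, sit = 0.55, stand = 1)
.POSTURE_BAND <- list(lay = c(0.7, 0.9), sit = c(1.1, 1.4),
                      stand = c(2.9, 3.4))
.WALK_BAND <- c(1.5, 2.5)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Default group-effect map for the synthetic cohort
#'
#' Schedule-parameter means per outcome group, seeded from the published
#' community/hospital time-percentage profile of this population (laying
#' dominates the hospital group at ~61% of uptime, standing the community
#' group at ~44%) and the resident-room activity-intensity contrast
#' (standardized difference 1.25 under a common SD). Each entry is
#' `c(community, hospital, sd)` on the schedule-parameter scale.
#'
#' @return Named list of `c(community, hospital, sd)` triples for
#'   `standingTimePct`, `sittingTimePct`, `layingTimePct`, `walkingTimePct`,
#'   `activeTimePct` (percent of uptime) and `residentRoomIntensity`
#'   (cm/s^2 per minute scale).
#' @examples
#' defaultGroupEffects()$layingTimePct
#' @export
defaultGroupEffects <- function() {
  list(
    standingTimePct = c(community = 44.22, hospital = 32.68, sd = 7.63),
    sittingTimePct = c(community = 8.60, hospital = 6.16, sd = 7.88),
    layingTimePct = c(community = 46.83, hospital = 60.99, sd = 10.49),
    walkingTimePct = c(community = 0.35, hospital = 0.15, sd = 0.41),
    activeTimePct = c(community = 12.92, hospital = 6.94, sd = 5.41),
    residentRoomIntensity = c(community = 43.32, hospital = 26.99, sd = 13.06))
}

#' Default beacon layout
#'
#' A two-room deployment: resident room (two beds, toilet, chair) and therapy
#' room (two therapy beds, bike, small table, resistance-band station, wall).
#' Beacons are spaced >= 3.5 m so the nearest-beacon rule is geometrically
#' identifiable.
#'
#' @return A [BeaconLayout-class].
#' @export
defaultBeaconLayout <- function() {
  beacons <- data.frame(
    beaconId = paste0("b_", c(.RESIDENT_LOCS, .THERAPY_LOCS)),
    locationId = c(.RESIDENT_LOCS, .THERAPY_LOCS),
    x = c(0, 3.5, 0, 3.5, 0, 4, 8, 0, 4, 8),
    y = c(0, 0, 4, 4, 12, 12, 12, 16, 16, 16))
  rooms <- c(rep("resident", length(.RESIDENT_LOCS)),
             rep("therapy", length(.THERAPY_LOCS)))
  names(rooms) <- c(.RESIDENT_LOCS, .THERAPY_LOCS)
  beaconLayout(beacons, rooms)
}

.locationRoom <- function(location) {
  ifelse(location %in% .RESIDENT_LOCS, "resident", "therapy")
}

#' Draw per-patient schedule parameters
#'
#' Draws one patient's schedule parameters (posture/motion dwell percentages,
#' resident-room activity intensity, therapy-session minutes) from the
#' group-effect map of `config`. The three posture percentages are
#' renormalized to share `100 - walking` so the exclusive dwell partition is
#' exact.
#'
#' @param config A [CohortConfig-class].
#' @param outcome `"community"` or `"hospital"`.
#' @return Named list of drawn parameters.
#' @export
drawPatientParameters <- function(config, outcome) {
  if (!outcome %in% c("community", "hospital"))
    stop("outcome must be 'community' or 'hospital', got '", outcome, "'")
  ge <- config@groupEffects
  draw <- function(name, lo, hi) {
    g <- ge[[name]]
    .clamp(stats::rnorm(1L, g[[outcome]], g[["sd"]]), lo, hi)
  }
  walk <- draw("walkingTimePct", 0.02, 3)
  stand <- draw("standingTimePct", 5, 90)
  sit <- draw("sittingTimePct", 0.5, 60)
  lay <- draw("layingTimePct", 5, 95)
  norm <- (100 - walk) / (stand + sit + lay)
  active <- draw("activeTimePct", walk + 0.5, 60)
  list(standPct = stand * norm, sitPct = sit * norm, layPct = lay * norm,
       walkPct = walk, activePct = active,
       residentIntensity = draw("residentRoomIntensity", 8, 120),
       therapyMin = .clamp(stats::rnorm(1L, config@therapyMeanMin,
                                        config@therapySdMin), 30, 90))
}

## chop [from, to] into dwell segments; draw() returns one row per call
.chopInterval <- function(from, to, minDur, drawRow) {
  rows <- list(); t <- from; i <- 0L
  while (t < to - 1e-6) {
    i <- i + 1L
    row <- drawRow()
    dur <- min(row$dur, to - t)
    if (to - (t + dur) < minDur) dur <- to - t  # absorb slivers
    rows[[i]] <- data.frame(start = t, end = t + dur,
                            location = row$location, posture = row$posture,
                            motion = row$motion)
    t <- t + dur
  }
  do.call(rbind, rows)
}

#' Generate a ground-truth protocol day
#'
#' Builds one patient-day schedule under the wear protocol: the day spans
#' 09:00--18:00, contains exactly one therapy-room block with duration drawn
#' near one hour, and fills the remaining time with resident-room dwell
#' segments whose posture/motion mix follows the (group-dependent) drawn
#' dwell fractions. The wear mask applies a Bernoulli early-removal dropout
#' (about half of patient-days end early) and an occasional mid-day off-wrist
#' gap, so some days fall below the 4-hour inclusion floor.
#'
#' @param config A [CohortConfig-class].
#' @param outcome Group label, `"community"` or `"hospital"`.
#' @param patientId,dayIndex Provenance for the schedule.
#' @param params Optional pre-drawn parameter list from
#'   [drawPatientParameters()]; drawn afresh when `NULL`.
#' @return A [ProtocolSchedule-class].
#' @examples
#' set.seed(1)
#' sch <- makeProtocolSchedule(cohortConfig(), "community")
#' head(segments(sch))
#' @export
makeProtocolSchedule <- function(config, outcome, patientId = "P000",
                                 dayIndex = 1L, params = NULL) {
  if (is.null(params)) params <- drawPatientParameters(config, outcome)
  s0 <- config@dayStart; s1 <- config@dayEnd
  span <- s1 - s0
  thDur <- min(params$therapyMin * 60, 0.4 * span)
  thLo <- s0 + min(3600, 0.15 * span)
  thHi <- max(thLo + 1, s1 - thDur - min(1800, 0.1 * span))
  thStart <- stats::runif(1L, thLo, thHi)
  pWalk <- .clamp((params$walkPct / max(params$standPct, 1e-6)) * 9, 0, 0.5)
  pActive <- .clamp((params$activePct - params$walkPct) /
                      (100 - params$walkPct), 0.01, 0.9)

  drawResident <- function() {
    posture <- sample(c("stand", "sit", "lay"), 1L,
                      prob = c(params$standPct, params$sitPct, params$layPct))
    walk <- posture == "stand" && stats::runif(1L) < pWalk
    motion <- if (walk) "walk"
      else if (stats::runif(1L) < pActive) "active" else "idle"
    dur <- if (walk) stats::runif(1L, 20, 60)
      else .clamp(stats::rgamma(1L, shape = 2, scale = 180), 60, 1200)
    location <- switch(posture,
      lay = sample(c("resident_bed1", "resident_bed2"), 1L, prob = c(.7, .3)),
      sit = sample(c("chair", "resident_bed1"), 1L, prob = c(.6, .4)),
      stand = sample(c("toilet", "chair", "resident_bed1"), 1L,
                     prob = c(.4, .3, .3)))
    list(dur = dur, location = location, posture = posture, motion = motion)
  }
  drawTherapy <- function() {
    posture <- sample(c("stand", "sit"), 1L, prob = c(.55, .45))
    walk <- posture == "stand" && stats::runif(1L) < 0.05
    motion <- if (walk) "walk"
      else if (stats::runif(1L) < 0.8) "active" else "idle"
    dur <- if (walk) stats::runif(1L, 20, 40)
      else .clamp(stats::rgamma(1L, shape = 2, scale = 120), 60, 600)
    list(dur = dur, location = sample(.THERAPY_LOCS, 1L), posture = posture,
         motion = motion)
  }

  seg <- rbind(
    .chopInterval(s0, thStart, 30, drawResident),
    .chopInterval(thStart, thStart + thDur, 20, drawTherapy),
    .chopInterval(thStart + thDur, s1, 30, drawResident))
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL

  ## wear mask: early-removal dropout plus occasional mid-day gap
  wearEnd <- if (stats::runif(1L) < config@dropoutProb)
    s0 + stats::runif(1L, 2 * 3600, 8.8 * 3600) else s1
  wearEnd <- min(wearEnd, s1)
  wm <- data.frame(start = s0, end = wearEnd)
  if (stats::runif(1L) < config@gapProb && wearEnd - s0 > 3 * 3600) {
    gStart <- stats::runif(1L, s0 + 600, wearEnd - 3600)
    gEnd <- min(gStart + stats::runif(1L, 1200, 3600), wearEnd - 300)
    if (gEnd > gStart)
      wm <- data.frame(start = c(s0, gEnd), end = c(gStart, wearEnd))
  }

  new("ProtocolSchedule", patientId = patientId,
      dayIndex = as.integer(dayIndex), outcome = outcome, segments = seg,
      wearMask = wm, params = params)
}

## per-segment signal signature: gravity direction, oscillation amp/freq/phase
.segmentSignatures <- function(seg, params, config) {
  n <- nrow(seg)
  gdir <- matrix(0, n, 3L)
  amp <- freq <- phase <- numeric(n)
  room <- .locationRoom(seg$location)
  for (i in seq_len(n)) {
    g <- .POSTURE_GRAVITY[[seg$posture[i]]] + stats::rnorm(3L, 0, 0.04)
    gdir[i, ] <- g / sqrt(sum(g^2))
    phase[i] <- stats::runif(1L, 0, 2 * pi)
    if (seg$motion[i] == "walk") {
      amp[i] <- .clamp(stats::rnorm(1L, 1.5, 0.2), 0.8, 2.5)
      freq[i] <- stats::runif(1L, .WALK_BAND[1], .WALK_BAND[2])
    } else {
      band <- .POSTURE_BAND[[seg$posture[i]]]
      freq[i] <- stats::runif(1L, band[1], band[2])
      if (seg$motion[i] == "idle") {
        amp[i] <- .IDLE_AMP[[seg$posture[i]]] * config@microMovementScale
      } else {
        inten <- if (room[i] == "resident") params$residentIntensity
          else stats::runif(1L, 50, 120)
        amp[i] <- pi * inten / 200 *
          .ACTIVE_POSTURE_FACTOR[[seg$posture[i]]] *
          config@microMovementScale
      }
    }
  }
  list(gdir = gdir, amp = amp, freq = freq, phase = phase)
}

#' Simulate the wrist accelerometer stream for one schedule
#'
#' Synthesizes a 16 Hz (configurable) triaxial stream in g units: a 1 g
#' gravity vector whose orientation depends on posture, a sinusoidal dynamic
#' component along the gravity axis (walking oscillation in the 1.5--2.5 Hz
#' cadence band with a second harmonic; posture-banded micro-movement for
#' stationary segments, with amplitude set so idle segments fall below and
#' active segments above the 0.02 m/s^2 post-filter MAD threshold), and
#' white sensor noise. Samples are emitted only inside the wear mask and are
#' clipped to +/-2 g.
#'
#' @param schedule A [ProtocolSchedule-class].
#' @param config A [CohortConfig-class].
#' @return An [AccelStream-class]; empty for an empty schedule.
#' @export
simulateAccelerometer <- function(schedule, config) {
  seg <- segments(schedule); wm <- wearMask(schedule)
  empty <- accelStream(numeric(0), numeric(0), numeric(0), numeric(0),
                       patientId = schedule@patientId,
                       dayIndex = schedule@dayIndex)
  if (!nrow(seg) || !nrow(wm)) return(empty)
  fs <- config@sampleRate
  sigs <- .segmentSignatures(seg, schedule@params, config)
  nsd <- config@sensorNoise / .GRAVITY_MS2
  chunks <- vector("list", nrow(wm))
  for (w in seq_len(nrow(wm))) {
    t <- seq(wm$start[w], wm$end[w] - 1 / (2 * fs), by = 1 / fs)
    if (!length(t)) next
    si <- .clamp(findInterval(t, seg$start), 1L, nrow(seg))
    ax <- ay <- az <- numeric(length(t))
    for (s in unique(si)) {
      idx <- si == s
      tt <- t[idx]
      dyn <- sigs$amp[s] * sin(2 * pi * sigs$freq[s] * tt + sigs$phase[s])
      if (seg$motion[s] == "walk")
        dyn <- dyn + 0.3 * sigs$amp[s] *
          sin(4 * pi * sigs$freq[s] * tt + 2 * sigs$phase[s])
      scale <- 1 + dyn / .GRAVITY_MS2
      ax[idx] <- sigs$gdir[s, 1] * scale
      ay[idx] <- sigs$gdir[s, 2] * scale
      az[idx] <- sigs$gdir[s, 3] * scale
    }
    n <- length(t)
    if (nsd > 0) {
      ax <- ax + stats::rnorm(n, 0, nsd)
      ay <- ay + stats::rnorm(n, 0, nsd)
      az <- az + stats::rnorm(n, 0, nsd)
    }
    chunks[[w]] <- data.frame(t = t, ax = ax, ay = ay, az = az)
  }
  d <- do.call(rbind, chunks)
  if (is.null(d) || !nrow(d)) return(empty)
  accelStream(d$t, .clamp(d$ax, -2, 2), .clamp(d$ay, -2, 2),
              .clamp(d$az, -2, 2), patientId = schedule@patientId,
              dayIndex = schedule@dayIndex)
}

#' Expected RSSI at a distance under the log-distance path-loss model
#'
#' `rssi(d) = ref - 10 * n * log10(d / d_ref)`, anchored at the line-of-sight
#' calibration point (-66 dBm at 1 ft by default) with exponent `n`
#' (default 2, free-space-like). Distances below 0.15 m are floored to keep
#' the model finite at contact.
#'
#' @param distM Distance(s) in metres.
#' @param config A [CohortConfig-class] carrying the anchor and exponent.
#' @return Mean RSSI in dBm.
#' @examples
#' rssiAtDistance(0.3048, cohortConfig())  # -66 at 1 ft
#' @export
rssiAtDistance <- function(distM, config = cohortConfig()) {
  d <- pmax(distM, 0.15)
  config@rssiRefDbm -
    10 * config@pathLossExponent * log10(d / config@rssiRefDistM)
}

#' Simulate the BLE beacon observation stream for one schedule
#'
#' Every beacon in the layout advertises once per `advertInterval` (250 ms by
#' default) while the watch is worn. The mean RSSI follows a log-distance
#' path-loss model anchored at the line-of-sight calibration point (-66 dBm
#' at 1 ft by default) with exponent `pathLossExponent`, plus Gaussian noise.
#' The patient's position in each segment is the occupied location's beacon
#' position with a small random offset, so that beacon has the strongest mean
#' RSSI throughout the segment.
#'
#' @param schedule A [ProtocolSchedule-class].
#' @param layout A [BeaconLayout-class]; every schedule location must be in
#'   it.
#' @param config A [CohortConfig-class].
#' @return A [BeaconStream-class]; empty for an empty schedule.
#' @export
simulateRssi <- function(schedule, layout, config) {
  bt <- beaconTable(layout)
  if (!nrow(bt)) stop("beacon layout is empty")
  seg <- segments(schedule); wm <- wearMask(schedule)
  emptyEv <- data.frame(time = numeric(0), beaconId = character(0),
                        rssi = numeric(0))
  if (!nrow(seg) || !nrow(wm))
    return(beaconStream(emptyEv, patientId = schedule@patientId,
                        dayIndex = schedule@dayIndex))
  unknown <- setdiff(unique(seg$location), bt$locationId)
  if (length(unknown))
    stop("schedule location(s) not in layout: ",
         paste(unknown, collapse = ", "))
  ## patient position per segment: occupied beacon + small offset
  occ <- match(seg$location, bt$locationId)
  px <- bt$x[occ] + stats::rnorm(nrow(seg), 0, 0.4)
  py <- bt$y[occ] + stats::rnorm(nrow(seg), 0, 0.4)
  nb <- nrow(bt)
  chunks <- list(); k <- 0L
  for (w in seq_len(nrow(wm))) {
    t <- seq(wm$start[w], wm$end[w], by = config@advertInterval)
    if (!length(t)) next
    si <- .clamp(findInterval(t, seg$start), 1L, nrow(seg))
    for (s in unique(si)) {
      tt <- t[si == s]
      d <- sqrt((bt$x - px[s])^2 + (bt$y - py[s])^2)
      mu <- rssiAtDistance(d, config)
      nt <- length(tt)
      k <- k + 1L
      chunks[[k]] <- data.table::data.table(
        time = rep(tt, each = nb),
        beaconId = rep(bt$beaconId, times = nt),
        rssi = rep(mu, times = nt) +
          stats::rnorm(nt * nb, 0, config@rssiNoiseSd))
    }
  }
  ev <- as.data.frame(data.table::rbindlist(chunks))
  beaconStream(ev, patientId = schedule@patientId,
               dayIndex = schedule@dayIndex)
}

#' Draw cohort-level schedule parameters without simulating sensors
#'
#' Draws the per-patient schedule parameters for a whole cohort (outcome
#' labels plus the group-effect draws). This is the sampling layer used to
#' study the sampling distribution of estimated effect sizes at the study's
#' group imbalance without paying for waveform synthesis.
#'
#' @param config A [CohortConfig-class].
#' @return data.frame, one row per patient: `patientId`, `outcome` and the
#'   drawn parameters.
#' @export
drawCohortParameters <- function(config) {
  nC <- config@nCommunity; nH <- config@nHospital
  outcome <- c(rep("community", nC), rep("hospital", nH))
  n <- nC + nH
  if (!n)
    return(data.frame(patientId = character(0), outcome = character(0)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- drawPatientParameters(config, outcome[i])
    rows[[i]] <- data.frame(patientId = sprintf("P%03d", i),
                            outcome = outcome[i],
                            standPct = p$standPct, sitPct = p$sitPct,
                            layPct = p$layPct, walkPct = p$walkPct,
                            activePct = p$activePct,
                            residentIntensity = p$residentIntensity,
                            therapyMin = p$therapyMin)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic sensor cohort
#'
#' Draws `nCommunity + nHospital` patients with outcome-dependent schedule
#' parameters, builds `days` candidate protocol days per patient, and
#' (optionally) simulates the accelerometer and beacon streams for each
#' patient-day. Seeded from `config@seed`, so identical configurations yield
#' bit-identical cohorts.
#'
#' @param config A [CohortConfig-class].
#' @param days Candidate days per patient (the first-3-days baseline rule
#'   needs at least 3).
#' @param simulateStreams Simulate the 16 Hz / RSSI streams (`TRUE`) or stop
#'   at ground-truth schedules (`FALSE`, cheap; used for schedule-level
#'   studies).
#' @param layout A [BeaconLayout-class].
#' @return A [SensorCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nCommunity = 2, nHospital = 1),
#'                       days = 1, simulateStreams = FALSE)
#' cohortMetadata(coh)
#' @export
generateCohort <- function(config, days = 3L, simulateStreams = TRUE,
                           layout = defaultBeaconLayout()) {
  validObject(config)
  set.seed(config@seed)
  nC <- config@nCommunity; nH <- config@nHospital
  n <- nC + nH
  if (n == 0L) {
    warning("empty cohort requested (0 patients)")
    return(new("SensorCohort", schedules = list(), accel = list(),
               beacons = list(), layout = layout,
               metadata = data.frame(patientId = character(0),
                                     day = integer(0), outcome = character(0),
                                     uptimeMin = numeric(0)),
               config = config))
  }
  outcome <- c(rep("community", nC), rep("hospital", nH))
  scheds <- accs <- becs <- list()
  md <- vector("list", n * days)
  r <- 0L
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    params <- drawPatientParameters(config, outcome[i])
    for (d in seq_len(days)) {
      key <- sprintf("%s.%d", pid, d)
      sch <- makeProtocolSchedule(config, outcome[i], patientId = pid,
                                  dayIndex = d, params = params)
      scheds[[key]] <- sch
      if (simulateStreams) {
        accs[[key]] <- simulateAccelerometer(sch, config)
        becs[[key]] <- simulateRssi(sch, layout, config)
      }
      wm <- wearMask(sch)
      r <- r + 1L
      md[[r]] <- data.frame(patientId = pid, day = d, outcome = outcome[i],
                            uptimeMin = sum(wm$end - wm$start) / 60,
                            residentIntensity = params$residentIntensity,
                            standPct = params$standPct,
                            layPct = params$layPct,
                            walkPct = params$walkPct,
                            activePct = params$activePct)
    }
  }
  new("SensorCohort", schedules = scheds, accel = accs, beacons = becs,
      layout = layout, metadata = do.call(rbind, md), config = config)
}
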