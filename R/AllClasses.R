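#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## CohortConfig
## ---------------------------------------------------------------------------

#' Cohort simulation configuration
#'
#' Holds every tunable of the synthetic cohort generator. Defaults encode the
#' study protocol the generator emulates: a 09:00--18:00 wear day, a daily
#' therapy-room session near one hour, a 16 Hz +/-2 g wrist accelerometer,
#' beacons advertising every 250 ms, and outcome-dependent group means for the
#' schedule parameters (posture/motion dwell fractions and resident-room
#' activity intensity).
#'
#' @slot nCommunity,nHospital Number of patients per outcome group.
#' @slot seed Integer seed used by [generateCohort()].
#' @slot groupEffects Named list; each element is
#'   `c(community = , hospital = , sd = )` giving the group means and common
#'   SD of one schedule parameter (see [defaultGroupEffects()]).
#' @slot rssiNoiseSd Gaussian RSSI noise SD in dBm.
#' @slot advertInterval Beacon advertisement interval in seconds.
#' @slot sampleRate Accelerometer sample rate in Hz.
#' @slot dropoutProb Per-day probability that the watch is removed early.
#' @slot gapProb Per-day probability of a mid-day off-wrist gap.
#' @slot sensorNoise Accelerometer white-noise SD in m/s^2.
#' @slot microMovementScale Multiplier on idle/active micro-movement
#'   amplitudes (0 yields pure gravity in static segments).
#' @slot dayStart,dayEnd Protocol day span, seconds since midnight.
#' @slot therapyMeanMin,therapySdMin Therapy-session duration distribution
#'   (minutes).
#' @slot pathLossExponent Log-distance path-loss exponent.
#' @slot rssiRefDbm,rssiRefDistM Path-loss anchor: mean RSSI at the reference
#'   distance (default -66 dBm at 1 ft).
#' @seealso [cohortConfig()]
#' @export
setClass("CohortConfig",
  representation(
    nCommunity = "integer", nHospital = "integer", seed = "integer",
    groupEffects = "list", rssiNoiseSd = "numeric",
    advertInterval = "numeric", sampleRate = "numeric",
    dropoutProb = "numeric", gapProb = "numeric", sensorNoise = "numeric",
    microMovementScale = "numeric",
    dayStart = "numeric", dayEnd = "numeric",
    therapyMeanMin = "numeric", therapySdMin = "numeric",
    pathLossExponent = "numeric", rssiRefDbm = "numeric",
    rssiRefDistM = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nCommunity < 0L || object@nHospital < 0L)
    msg <- c(msg, "group counts must be >= 0")
  if (object@advertInterval <= 0)
    msg <- c(msg, "advertInterval must be > 0")
  if (object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be > 0")
  if (object@rssiNoiseSd < 0)
    msg <- c(msg, "rssiNoiseSd must be >= 0")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    msg <- c(msg, "dropoutProb must be in [0, 1]")
  if (object@gapProb < 0 || object@gapProb > 1)
    msg <- c(msg, "gapProb must be in [0, 1]")
  if (object@dayStart >= object@dayEnd)
    msg <- c(msg, "dayStart must precede dayEnd")
  for (nm in names(object@groupEffects)) {
    ge <- object@groupEffects[[nm]]
    if (length(ge) != 3L || !all(c("community", "hospital", "sd") %in% names(ge)))
      msg <- c(msg, sprintf("groupEffects[['%s']] needs community/hospital/sd", nm))
    else if (ge[["sd"]] <= 0)
      msg <- c(msg, sprintf("groupEffects[['%s']] sd must be > 0", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortConfig Constructor with study-protocol defaults.
#' @param nCommunity,nHospital,seed,groupEffects,rssiNoiseSd,advertInterval
#'   See slots.
#' @param sampleRate,dropoutProb,gapProb,sensorNoise,microMovementScale
#'   See slots.
#' @param dayStart,dayEnd,therapyMeanMin,therapySdMin See slots.
#' @param pathLossExponent,rssiRefDbm,rssiRefDistM See slots.
#' @examples
#' cfg <- cohortConfig(nCommunity = 2, nHospital = 1, seed = 7)
#' cfg
#' @export
cohortConfig <- function(nCommunity = 145L, nHospital = 9L, seed = 40L,
                         groupEffects = defaultGroupEffects(),
                         rssiNoiseSd = 4, advertInterval = 0.25,
                         sampleRate = 16, dropoutProb = 0.5, gapProb = 0.2,
                         sensorNoise = 0.005, microMovementScale = 1,
                         dayStart = 9 * 3600, dayEnd = 18 * 3600,
                         therapyMeanMin = 60, therapySdMin = 8,
                         pathLossExponent = 2, rssiRefDbm = -66,
                         rssiRefDistM = .FOOT_M) {
  new("CohortConfig",
      nCommunity = as.integer(nCommunity), nHospital = as.integer(nHospital),
      seed = as.integer(seed), groupEffects = groupEffects,
      rssiNoiseSd = rssiNoiseSd, advertInterval = advertInterval,
      sampleRate = sampleRate, dropoutProb = dropoutProb, gapProb = gapProb,
      sensorNoise = sensorNoise, microMovementScale = microMovementScale,
      dayStart = dayStart, dayEnd = dayEnd,
      therapyMeanMin = therapyMeanMin, therapySdMin = therapySdMin,
      pathLossExponent = pathLossExponent, rssiRefDbm = rssiRefDbm,
      rssiRefDistM = rssiRefDistM)
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nCommunity, "community /", object@nHospital,
      "hospital patients, seed", object@seed, "\n")
  cat("  day", .fmtClock(object@dayStart), "-", .fmtClock(object@dayEnd),
      "| accel", object@sampleRate, "Hz | advert",
      object@advertInterval * 1000, "ms | RSSI noise",
      object@rssiNoiseSd, "dBm\n")
  cat("  group-effect parameters:",
      paste(names(object@groupEffects), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ProtocolSchedule
## ---------------------------------------------------------------------------

#' Ground-truth daily protocol schedule
#'
#' One patient-day of ground truth for the simulator: an ordered,
#' non-overlapping set of activity segments (location, posture, motion) over
#' the 09:00--18:00 protocol day plus the worn intervals of the watch.
#' Walking only ever occurs while standing.
#'
#' @slot patientId,dayIndex Provenance.
#' @slot outcome `"community"` or `"hospital"`.
#' @slot segments data.frame with `start`, `end` (seconds since midnight),
#'   `location`, `posture` (`stand`/`sit`/`lay`), `motion`
#'   (`walk`/`active`/`idle`).
#' @slot wearMask data.frame with `start`, `end` of worn intervals.
#' @slot params Named list of the drawn per-day schedule parameters
#'   (dwell fractions, resident-room intensity, therapy minutes).
#' @export
setClass("ProtocolSchedule",
  representation(patientId = "character", dayIndex = "integer",
                 outcome = "character", segments = "data.frame",
                 wearMask = "data.frame", params = "list"))

setValidity("ProtocolSchedule", function(object) {
  seg <- object@segments
  msg <- character()
  need <- c("start", "end", "location", "posture", "motion")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(seg)) {
    if (any(seg$end <= seg$start))
      msg <- c(msg, "segments must have positive duration")
    if (is.unsorted(seg$start, strictly = TRUE) ||
        any(seg$start[-1] < seg$end[-nrow(seg)] - 1e-9))
      msg <- c(msg, "segments must be ordered and non-overlapping")
    if (!all(seg$posture %in% c("stand", "sit", "lay")))
      msg <- c(msg, "posture must be stand/sit/lay")
    if (!all(seg$motion %in% c("walk", "active", "idle")))
      msg <- c(msg, "motion must be walk/active/idle")
    if (any(seg$motion == "walk" & seg$posture != "stand"))
      msg <- c(msg, "walk motion requires stand posture")
  }
  wm <- object@wearMask
  if (!all(c("start", "end") %in% names(wm)))
    return("wearMask must have columns start, end")
  if (nrow(wm) && nrow(seg)) {
    if (any(wm$end <= wm$start))
      msg <- c(msg, "wear intervals must have positive duration")
    if (min(wm$start) < min(seg$start) - 1e-9 ||
        max(wm$end) > max(seg$end) + 1e-9)
      msg <- c(msg, "wear intervals must lie within the scheduled day")
  }
  if (!object@outcome %in% c("community", "hospital"))
    msg <- c(msg, "outcome must be 'community' or 'hospital'")
  if (length(msg)) msg else TRUE
})

#' @rdname rehabsense-accessors
#' @export
setMethod("patientId", "ProtocolSchedule", function(x) x@patientId)
#' @rdname rehabsense-accessors
#' @export
setMethod("dayIndex", "ProtocolSchedule", function(x) x@dayIndex)
#' @rdname rehabsense-accessors
#' @export
setMethod("segments", "ProtocolSchedule", function(x) x@segments)
#' @rdname rehabsense-accessors
#' @export
setMethod("wearMask", "ProtocolSchedule", function(x) x@wearMask)

setMethod("show", "ProtocolSchedule", function(object) {
  seg <- object@segments
  wm <- object@wearMask
  cat("ProtocolSchedule", object@patientId, "day", object@dayIndex,
      sprintf("(%s)\n", object@outcome))
  if (nrow(seg))
    cat("  ", nrow(seg), "segments ", .fmtClock(min(seg$start)), "-",
        .fmtClock(max(seg$end)), "\n", sep = "")
  cat("  worn ", round(sum(wm$end - wm$start) / 60), " min in ",
      nrow(wm), " interval(s)\n", sep = "")
})

## ---------------------------------------------------------------------------
## AccelStream
## ---------------------------------------------------------------------------

#' Triaxial accelerometer stream
#'
#' Timestamped triaxial acceleration for one patient-day, in g units with
#' gravity included, nominally sampled at 16 Hz and clipped to +/-2 g.
#' Timestamps are seconds since midnight and strictly increasing; non-wear
#' gaps appear as missing spans, never as padded samples.
#'
#' @slot patientId,dayIndex Provenance.
#' @slot time Numeric, strictly increasing timestamps (s).
#' @slot ax,ay,az Acceleration per axis in g.
#' @seealso [accelStream()], [simulateAccelerometer()]
#' @export
setClass("AccelStream",
  representation(patientId = "character", dayIndex = "integer",
                 time = "numeric", ax = "numeric", ay = "numeric",
                 az = "numeric"))

setValidity("AccelStream", function(object) {
  n <- length(object@time)
  msg <- character()
  if (length(object@ax) != n || length(object@ay) != n ||
      length(object@az) != n)
    msg <- c(msg, "time/ax/ay/az must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (n && max(abs(c(object@ax, object@ay, object@az))) > 2 + 1e-9)
    msg <- c(msg, "acceleration must lie within +/-2 g")
  if (length(msg)) msg else TRUE
})

#' Construct an accelerometer stream
#'
#' @param time,ax,ay,az Equal-length numeric vectors (s; g).
#' @param patientId,dayIndex Provenance.
#' @return An [AccelStream-class] object.
#' @export
accelStream <- function(time, ax, ay, az, patientId = "P000",
                        dayIndex = 1L) {
  new("AccelStream", patientId = patientId, dayIndex = as.integer(dayIndex),
      time = as.numeric(time), ax = as.numeric(ax), ay = as.numeric(ay),
      az = as.numeric(az))
}

#' @rdname rehabsense-accessors
#' @export
setMethod("patientId", "AccelStream", function(x) x@patientId)
#' @rdname rehabsense-accessors
#' @export
setMethod("dayIndex", "AccelStream", function(x) x@dayIndex)

#' @describeIn AccelStream Number of samples.
#' @param x An `AccelStream`.
#' @export
setMethod("length", "AccelStream", function(x) length(x@time))

#' @describeIn AccelStream Samples as a data.frame
#'   (`timestamp_s, ax_g, ay_g, az_g`).
#' @param row.names,optional,... Passed on per the generic (unused).
#' @export
setMethod("as.data.frame", "AccelStream",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(timestamp_s = x@time, ax_g = x@ax, ay_g = x@ay, az_g = x@az)
  })

setMethod("show", "AccelStream", function(object) {
  n <- length(object@time)
  cat("AccelStream", object@patientId, "day", object@dayIndex, ":",
      n, "samples")
  if (n) cat(" over", round((max(object@time) - min(object@time)) / 60),
             "min")
  cat("\n")
})

## ---------------------------------------------------------------------------
## BeaconStream
## ---------------------------------------------------------------------------

#' BLE beacon observation stream
#'
#' Timestamped `(beacon_id, RSSI)` advertisement observations for one
#' patient-day. Timestamps are non-decreasing (several beacons are heard in
#' the same advertisement slot); RSSI values are finite dBm.
#'
#' @slot patientId,dayIndex Provenance.
#' @slot events data.frame with `time` (s), `beaconId`, `rssi` (dBm).
#' @seealso [beaconStream()], [simulateRssi()]
#' @export
setClass("BeaconStream",
  representation(patientId = "character", dayIndex = "integer",
                 events = "data.frame"))

setValidity("BeaconStream", function(object) {
  ev <- object@events
  if (!all(c("time", "beaconId", "rssi") %in% names(ev)))
    return("events must have columns time, beaconId, rssi")
  msg <- character()
  if (nrow(ev)) {
    if (is.unsorted(ev$time))
      msg <- c(msg, "event times must be non-decreasing")
    if (!all(is.finite(ev$rssi)))
      msg <- c(msg, "rssi values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a beacon observation stream
#'
#' @param events data.frame with columns `time`, `beaconId`, `rssi`.
#' @param patientId,dayIndex Provenance.
#' @return A [BeaconStream-class] object.
#' @export
beaconStream <- function(events, patientId = "P000", dayIndex = 1L) {
  new("BeaconStream", patientId = patientId, dayIndex = as.integer(dayIndex),
      events = as.data.frame(events))
}

#' @rdname rehabsense-accessors
#' @export
setMethod("beaconEvents", "BeaconStream", function(x) x@events)
#' @rdname rehabsense-accessors
#' @export
setMethod("patientId", "BeaconStream", function(x) x@patientId)
#' @rdname rehabsense-accessors
#' @export
setMethod("dayIndex", "BeaconStream", function(x) x@dayIndex)

setMethod("show", "BeaconStream", function(object) {
  cat("BeaconStream", object@patientId, "day", object@dayIndex, ":",
      nrow(object@events), "events from",
      length(unique(object@events$beaconId)), "beacons\n")
})

## ---------------------------------------------------------------------------
## BeaconLayout
## ---------------------------------------------------------------------------

#' Beacon deployment layout
#'
#' Where the beacons are mounted: each beacon sits at a named location of
#' interest with 2-D coordinates, and each location belongs to one room
#' (`resident` or `therapy`).
#'
#' @slot beacons data.frame with `beaconId`, `locationId`, `x`, `y` (m).
#' @slot rooms Named character: `locationId -> room`.
#' @seealso [beaconLayout()], [defaultBeaconLayout()]
#' @export
setClass("BeaconLayout",
  representation(beacons = "data.frame", rooms = "character"))

setValidity("BeaconLayout", function(object) {
  b <- object@beacons
  if (!all(c("beaconId", "locationId", "x", "y") %in% names(b)))
    return("beacons must have columns beaconId, locationId, x, y")
  msg <- character()
  if (anyDuplicated(b$beaconId))
    msg <- c(msg, "beacon ids must be unique")
  miss <- setdiff(unique(b$locationId), names(object@rooms))
  if (length(miss))
    msg <- c(msg, paste("locations without a room:",
                        paste(miss, collapse = ", ")))
  if (length(object@rooms) &&
      !all(object@rooms %in% c("resident", "therapy")))
    msg <- c(msg, "rooms must be 'resident' or 'therapy'")
  if (length(msg)) msg else TRUE
})

#' Construct a beacon layout
#'
#' @param beacons data.frame with `beaconId`, `locationId`, `x`, `y`.
#' @param rooms Named character vector mapping each `locationId` to
#'   `"resident"` or `"therapy"`.
#' @return A [BeaconLayout-class] object.
#' @export
beaconLayout <- function(beacons, rooms) {
  new("BeaconLayout", beacons = as.data.frame(beacons), rooms = rooms)
}

#' @rdname rehabsense-accessors
#' @export
setMethod("beaconTable", "BeaconLayout", function(x) x@beacons)
#' @rdname rehabsense-accessors
#' @export
setMethod("roomOf", "BeaconLayout", function(x) x@rooms)

setMethod("show", "BeaconLayout", function(object) {
  cat("BeaconLayout:", nrow(object@beacons), "beacons,",
      sum(object@rooms == "resident"), "resident /",
      sum(object@rooms == "therapy"), "therapy locations\n")
})

## ---------------------------------------------------------------------------
## FilterSpec
## ---------------------------------------------------------------------------

#' Band-pass filter specification
#'
#' The study's pre-processing filter: a 5th-order Butterworth band-pass with
#' 0.5 and 8 Hz cut-offs applied to the 16 Hz signal magnitude. The upper
#' cut-off may sit at the Nyquist frequency (as it does at 16 Hz sampling);
#' the filter is realized with the closed-form Butterworth magnitude response
#' applied zero-phase in the frequency domain, which is well defined there.
#'
#' @slot order Filter order (poles of the low-pass prototype).
#' @slot low,high Cut-off frequencies in Hz (-3 dB points).
#' @slot sampleRate Sample rate in Hz.
#' @seealso [filterSpec()], [bandpassFilter()]
#' @export
setClass("FilterSpec",
  representation(order = "integer", low = "numeric", high = "numeric",
                 sampleRate = "numeric"))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (!(object@low > 0 && object@low < object@high))
    msg <- c(msg, "need 0 < low < high")
  if (object@high > object@sampleRate / 2 + 1e-9)
    msg <- c(msg, "high cut-off cannot exceed the Nyquist frequency")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterSpec Constructor with the study defaults
#'   (order 5, 0.5--8 Hz, 16 Hz).
#' @param order,low,high,sampleRate See slots.
#' @examples
#' filterSpec()
#' @export
filterSpec <- function(order = 5L, low = 0.5, high = 8, sampleRate = 16) {
  new("FilterSpec", order = as.integer(order), low = low, high = high,
      sampleRate = sampleRate)
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec: order-%d Butterworth band-pass %.2g-%.2g Hz @ %g Hz\n",
              object@order, object@low, object@high, object@sampleRate))
})

## ---------------------------------------------------------------------------
## HierarchicalModel
## ---------------------------------------------------------------------------

#' Hierarchical activity-recognition model
#'
#' The three-stage hierarchy: stage 1 separates walking from stationary
#' windows (learned), stage 2 splits stationary windows into active/idle by
#' the MAD threshold, stage 3 assigns a posture (stand/sit/lay) to stationary
#' windows (learned).
#'
#' @slot stage1,stage3 Fitted classifiers over the 7 window features.
#' @slot algorithm Algorithm identifier (currently `"randomForest"`).
#' @slot seed Training seed.
#' @slot featureNames Feature columns the model expects.
#' @slot cvStats Per-stage cross-validation summaries (precision/recall/F1
#'   per class), as recorded at training time.
#' @seealso [trainHierarchicalClassifier()], [classifyWindows()]
#' @export
setClass("HierarchicalModel",
  representation(stage1 = "ANY", stage3 = "ANY", algorithm = "character",
                 seed = "integer", featureNames = "character",
                 cvStats = "list"))

setMethod("show", "HierarchicalModel", function(object) {
  cat("HierarchicalModel (", object@algorithm, ", seed ", object@seed,
      ")\n", sep = "")
  cat("  stage 1: walking vs stationary | stage 2: MAD threshold |",
      "stage 3: stand/sit/lay\n")
  if (length(object@cvStats))
    cat("  CV recorded for:", paste(names(object@cvStats), collapse = ", "),
        "\n")
})

## ---------------------------------------------------------------------------
## SensorCohort
## ---------------------------------------------------------------------------

#' Synthetic sensor cohort
#'
#' A generated cohort: per patient-day ground-truth schedules and (optionally)
#' the simulated accelerometer and beacon streams, plus patient metadata with
#' outcome labels and the drawn schedule parameters for label-recovery tests.
#'
#' @slot schedules,accel,beacons Lists keyed `"<patientId>.<day>"`.
#' @slot layout The [BeaconLayout-class] used.
#' @slot metadata data.frame: one row per patient-day (`patientId`, `day`,
#'   `outcome`, `uptimeMin`, drawn parameters).
#' @slot config The generating [CohortConfig-class].
#' @seealso [generateCohort()]
#' @export
setClass("SensorCohort",
  representation(schedules = "list", accel = "list", beacons = "list",
                 layout = "BeaconLayout", metadata = "data.frame",
                 config = "CohortConfig"))

#' @rdname rehabsense-accessors
#' @export
setMethod("cohortMetadata", "SensorCohort", function(x) x@metadata)
#' @rdname rehabsense-accessors
#' @export
setMethod("accelStreams", "SensorCohort", function(x) x@accel)
#' @rdname rehabsense-accessors
#' @export
setMethod("beaconStreams", "SensorCohort", function(x) x@beacons)
#' @rdname rehabsense-accessors
#' @export
setMethod("schedules", "SensorCohort", function(x) x@schedules)

setMethod("show", "SensorCohort", function(object) {
  md <- object@metadata
  cat("SensorCohort:", length(unique(md$patientId)), "patients (",
      sum(!duplicated(md$patientId) & md$outcome == "community"),
      "community /",
      sum(!duplicated(md$patientId) & md$outcome == "hospital"),
      "hospital ),", nrow(md), "patient-days\n")
  cat("  streams simulated:", length(object@accel) > 0, "\n")
})
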