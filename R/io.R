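#' @include published-summaries.R
NULL

.checkHeader <- function(d, need, path) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
}

.checkNumericRows <- function(d, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) | is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("%s: malformed value in column '%s' at data line(s) %s",
                   path, col,
                   paste(utils::head(bad + 1L, 5L), collapse = ", ")))
    d[[col]] <- v
  }
  d
}

#' Read / write accelerometer CSV streams
#'
#' The accelerometer CSV dialect is `timestamp_s,ax_g,ay_g,az_g`. Reading
#' validates the header, numeric content (malformed rows are reported with
#' line numbers) and the strictly-increasing timestamp invariant; an empty
#' file with a header yields an empty stream.
#'
#' @param path File path.
#' @param patientId,dayIndex Provenance attached to the stream.
#' @return [readAccelCsv()] returns an [AccelStream-class].
#' @export
readAccelCsv <- function(path, patientId = "P000", dayIndex = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path, colClasses = "character"))
  .checkHeader(d, c("timestamp_s", "ax_g", "ay_g", "az_g"), path)
  d <- .checkNumericRows(d, c("timestamp_s", "ax_g", "ay_g", "az_g"), path)
  if (nrow(d) > 1L && any(diff(d$timestamp_s) <= 0))
    stop(path, ": timestamps are not strictly increasing")
  accelStream(d$timestamp_s, d$ax_g, d$ay_g, d$az_g, patientId, dayIndex)
}

#' @rdname readAccelCsv
#' @param stream An [AccelStream-class] to serialize.
#' @export
writeAccelCsv <- function(stream, path) {
  data.table::fwrite(as.data.frame(stream), path)
  invisible(path)
}

#' Read / write beacon observation CSV streams
#'
#' Dialect `timestamp_s,beacon_id,rssi_dbm`; timestamps must be
#' non-decreasing and RSSI finite.
#'
#' @param path File path.
#' @param patientId,dayIndex Provenance.
#' @return [readBeaconCsv()] returns a [BeaconStream-class].
#' @export
readBeaconCsv <- function(path, patientId = "P000", dayIndex = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path, colClasses = "character"))
  .checkHeader(d, c("timestamp_s", "beacon_id", "rssi_dbm"), path)
  d <- .checkNumericRows(d, c("timestamp_s", "rssi_dbm"), path)
  if (nrow(d) > 1L && is.unsorted(d$timestamp_s))
    stop(path, ": timestamps are not non-decreasing")
  beaconStream(data.frame(time = d$timestamp_s, beaconId = d$beacon_id,
                          rssi = d$rssi_dbm), patientId, dayIndex)
}

#' @rdname readBeaconCsv
#' @param stream A [BeaconStream-class] to serialize.
#' @export
writeBeaconCsv <- function(stream, path) {
  ev <- beaconEvents(stream)
  data.table::fwrite(data.frame(timestamp_s = ev$time,
                                beacon_id = ev$beaconId,
                                rssi_dbm = ev$rssi), path)
  invisible(path)
}

#' Read / write a beacon layout CSV
#'
#' Dialect `beacon_id,location_id,room,x_m,y_m`, shared with the simulator.
#'
#' @param path File path.
#' @return [readBeaconLayoutCsv()] returns a [BeaconLayout-class].
#' @export
readBeaconLayoutCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path))
  .checkHeader(d, c("beacon_id", "location_id", "room", "x_m", "y_m"), path)
  rooms <- stats::setNames(as.character(d$room), d$location_id)
  rooms <- rooms[!duplicated(names(rooms))]
  beaconLayout(data.frame(beaconId = d$beacon_id,
                          locationId = d$location_id, x = d$x_m, y = d$y_m),
               rooms)
}

#' @rdname readBeaconLayoutCsv
#' @param layout A [BeaconLayout-class] to serialize.
#' @export
writeBeaconLayoutCsv <- function(layout, path) {
  bt <- beaconTable(layout)
  data.table::fwrite(data.frame(beacon_id = bt$beaconId,
                                location_id = bt$locationId,
                                room = unname(roomOf(layout)[bt$locationId]),
                                x_m = bt$x, y_m = bt$y), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable constants of the end-to-end pipeline with their study
#' defaults: 16 Hz sampling, 10-s windows with 1-s overlap, the 0.5--8 Hz
#' order-5 Butterworth band, the 0.02 m/s^2 MAD threshold, the
#' \[-100, -50\] dBm RSSI clip, the 240-min uptime and 15-min therapy
#' inclusion minima, and the intensity cutoff of 90. Configurations
#' round-trip losslessly through YAML.
#'
#' @param seed Pipeline seed.
#' @param nCommunity,nHospital Synthetic cohort sizes.
#' @param days Candidate days per patient.
#' @param sampleRate,windowSec,overlapSec,filterLow,filterHigh,filterOrder
#'   Signal-processing constants.
#' @param madThreshold Active/idle threshold (m/s^2).
#' @param rssiClip RSSI clipping range (dBm).
#' @param minUptimeMin,minTherapyMin,maxBaselineDay Inclusion criteria.
#' @param intensityCutoff Light vs moderate-to-vigorous boundary.
#' @return Named list of class `rehabsensePipelineConfig`.
#' @export
pipelineConfig <- function(seed = 40L, nCommunity = 6L, nHospital = 3L,
                           days = 3L, sampleRate = 16, windowSec = 10,
                           overlapSec = 1, filterLow = 0.5, filterHigh = 8,
                           filterOrder = 5L, madThreshold = 0.02,
                           rssiClip = c(-100, -50), minUptimeMin = 240,
                           minTherapyMin = 15, maxBaselineDay = 3L,
                           intensityCutoff = 90) {
  cfg <- list(seed = as.integer(seed), nCommunity = as.integer(nCommunity),
              nHospital = as.integer(nHospital), days = as.integer(days),
              sampleRate = sampleRate, windowSec = windowSec,
              overlapSec = overlapSec, filterLow = filterLow,
              filterHigh = filterHigh, filterOrder = as.integer(filterOrder),
              madThreshold = madThreshold, rssiClip = rssiClip,
              minUptimeMin = minUptimeMin, minTherapyMin = minTherapyMin,
              maxBaselineDay = as.integer(maxBaselineDay),
              intensityCutoff = intensityCutoff)
  class(cfg) <- "rehabsensePipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param cfg A pipeline configuration list to validate.
#' @export
validatePipelineConfig <- function(cfg) {
  need <- c("seed", "nCommunity", "nHospital", "days", "sampleRate",
            "windowSec", "overlapSec", "filterLow", "filterHigh",
            "filterOrder", "madThreshold", "rssiClip", "minUptimeMin",
            "minTherapyMin", "maxBaselineDay", "intensityCutoff")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("pipeline config is missing: ", paste(miss, collapse = ", "))
  .assertScalarNumber(cfg$sampleRate, "sampleRate", lower = 1e-9)
  .assertScalarNumber(cfg$madThreshold, "madThreshold", lower = 0)
  if (cfg$overlapSec >= cfg$windowSec)
    stop("overlapSec must be smaller than windowSec")
  if (length(cfg$rssiClip) != 2L || cfg$rssiClip[1] >= cfg$rssiClip[2])
    stop("rssiClip must be an increasing length-2 range")
  if (!(cfg$filterLow > 0 && cfg$filterLow < cfg$filterHigh &&
        cfg$filterHigh <= cfg$sampleRate / 2))
    stop("filter band must satisfy 0 < low < high <= Nyquist")
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$nCommunity <- as.integer(cfg$nCommunity)
  cfg$nHospital <- as.integer(cfg$nHospital)
  cfg$days <- as.integer(cfg$days)
  cfg$filterOrder <- as.integer(cfg$filterOrder)
  cfg$maxBaselineDay <- as.integer(cfg$maxBaselineDay)
  class(cfg) <- "rehabsensePipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}
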