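#' @include AllClasses.R
NULL

#' Clip RSSI values into the considered range
#'
#' Observed RSSI values are clamped into the closed `[-100, -50]` dBm range
#' considered for proximity inference; out-of-range values are clipped, not
#' discarded.
#'
#' @param rssi Finite RSSI value(s) in dBm.
#' @param range Length-2 numeric, the closed clipping range.
#' @return Clipped values.
#' @examples
#' clipRssi(c(-66, -110, -40))
#' @export
clipRssi <- function(rssi, range = c(-100, -50)) {
  if (any(!is.finite(rssi))) stop("rssi values must be finite")
  pmin(pmax(rssi, min(range)), max(range))
}

#' Per-beacon RSSI summary over a window
#'
#' Median of the clipped RSSI values each beacon produced inside
#' `[start, start + duration)`. Beacons with no events in the window are
#' absent from the summary; the median is robust to the dropout and
#' body-absorption noise BLE observations carry.
#'
#' @param events data.frame with `time`, `beaconId`, `rssi`.
#' @param start Window start (s).
#' @param duration Window duration (s), > 0.
#' @param range Clipping range passed to [clipRssi()].
#' @return Named numeric vector (beaconId -> median dBm); empty if no events.
#' @export
smoothRssi <- function(events, start, duration, range = c(-100, -50)) {
  if (duration <= 0) stop("window duration must be > 0")
  inWin <- events$time >= start & events$time < start + duration
  ev <- events[inWin, , drop = FALSE]
  if (!nrow(ev)) return(stats::setNames(numeric(0), character(0)))
  r <- tapply(clipRssi(ev$rssi, range), ev$beaconId, stats::median)
  stats::setNames(as.numeric(r), names(r))
}

#' Assign a window's location from per-beacon summaries
#'
#' Nearest-beacon rule: the beacon with the maximum summary RSSI marks the
#' occupied sublocation; ties break to the lexicographically smallest beacon
#' id. An empty summary yields `"unknown"` (and unknown room).
#'
#' @param summaries Named numeric vector from [smoothRssi()].
#' @param layout A [BeaconLayout-class] mapping every observed beacon id.
#' @return List with `rawLocation`, `canonicalLocation`, `room`.
#' @export
assignLocation <- function(summaries, layout) {
  if (!length(summaries))
    return(list(rawLocation = "unknown", canonicalLocation = "unknown",
                room = "unknown"))
  bt <- beaconTable(layout)
  miss <- setdiff(names(summaries), bt$beaconId)
  if (length(miss))
    stop("beacon id(s) not in layout: ", paste(miss, collapse = ", "))
  ord <- order(-summaries, names(summaries))
  winner <- names(summaries)[ord[1L]]
  raw <- bt$locationId[match(winner, bt$beaconId)]
  list(rawLocation = raw, canonicalLocation = aggregateLocation(raw),
       room = unname(roomOf(layout)[raw]))
}

#' Aggregate sublocations into canonical locations
#'
#' The reporting aggregation over the location vocabulary: shower, toilet
#' and sink count as bathroom; numbered walls as wall; the numbered beds of
#' each room as that room's bed; anything else maps to itself. `"unknown"`
#' passes through.
#'
#' @param raw Character vector of sublocation ids.
#' @param vocabulary Optional character vector; when given, any `raw` value
#'   outside it is an error.
#' @return Character vector of canonical location ids.
#' @examples
#' aggregateLocation(c("toilet", "wall2", "bike"))
#' @export
aggregateLocation <- function(raw, vocabulary = NULL) {
  raw <- as.character(raw)
  if (!is.null(vocabulary)) {
    bad <- setdiff(raw, c(vocabulary, "unknown"))
    if (length(bad))
      stop("location(s) outside the vocabulary: ",
           paste(unique(bad), collapse = ", "))
  }
  out <- raw
  out[raw %in% c("shower", "toilet", "sink")] <- "bathroom"
  out[grepl("^wall[0-9]+$", raw)] <- "wall"
  out[grepl("^therapy_bed[1-4]$", raw)] <- "therapy_bed"
  out[grepl("^resident_bed[12]$", raw)] <- "resident_bed"
  out
}

#' Localize every analysis window of a patient-day
#'
#' Assigns each window a location: events are bucketed to the most recent
#' window start, summarized per beacon with the clipped median, and the
#' nearest-beacon rule picks the sublocation, which is then aggregated and
#' mapped to its room. Windows without events are `"unknown"` but still
#' present, so the assignments partition the day.
#'
#' @param stream A [BeaconStream-class] (or its events data.frame).
#' @param windowStarts Window start times (s), as produced by
#'   [segmentWindows()] on the matching accelerometer stream.
#' @param layout A [BeaconLayout-class].
#' @param windowSec Window duration (s).
#' @param range RSSI clipping range.
#' @return data.frame with `startTime`, `rawLocation`, `canonicalLocation`,
#'   `room`, one row per window.
#' @export
localizeWindows <- function(stream, windowStarts, layout, windowSec = 10,
                            range = c(-100, -50)) {
  events <- if (is(stream, "BeaconStream")) beaconEvents(stream)
    else as.data.frame(stream)
  nw <- length(windowStarts)
  out <- data.frame(startTime = windowStarts,
                    rawLocation = rep("unknown", nw),
                    canonicalLocation = rep("unknown", nw),
                    room = rep("unknown", nw))
  if (!nw || !nrow(events)) return(out)
  bt <- beaconTable(layout)
  miss <- setdiff(unique(events$beaconId), bt$beaconId)
  if (length(miss))
    stop("beacon id(s) not in layout: ", paste(miss, collapse = ", "))
  ord <- order(windowStarts)
  starts <- windowStarts[ord]
  dt <- data.table::data.table(time = events$time,
                               beaconId = events$beaconId,
                               rssi = clipRssi(events$rssi, range))
  dt[, win := findInterval(time, starts)]
  dt <- dt[win >= 1L]
  dt <- dt[time < starts[win] + windowSec]
  if (!nrow(dt)) return(out)
  med <- dt[, list(rssi = stats::median(rssi)), by = list(win, beaconId)]
  data.table::setorder(med, win, -rssi, beaconId)
  top <- med[, utils::head(.SD, 1L), by = win]
  raw <- bt$locationId[match(top$beaconId, bt$beaconId)]
  rows <- ord[top$win]
  out$rawLocation[rows] <- raw
  out$canonicalLocation[rows] <- aggregateLocation(raw)
  out$room[rows] <- unname(roomOf(layout)[raw])
  out
}
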