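#' @include indoor-localization.R
NULL

.ACTIVITY_STATES <- c("walking", "standing", "sitting", "laying")

#' Watch wear time in minutes
#'
#' Total worn minutes of a day from its wear intervals; non-worn spans are
#' excluded by construction.
#'
#' @param wearMask data.frame with `start`, `end` in seconds.
#' @return Minutes (numeric scalar).
#' @examples
#' computeUptime(data.frame(start = c(0, 10000), end = c(7200, 19000)))
#' @export
computeUptime <- function(wearMask) {
  if (!nrow(wearMask)) return(0)
  sum(wearMask$end - wearMask$start) / 60
}

#' Select a patient's baseline day
#'
#' The earliest day within the first `maxDay` admission days satisfying both
#' inclusion rules -- at least `minUptimeMin` minutes of watch wear (4 h) and
#' at least `minTherapyMin` minutes of therapy-room wear (15 min). Patients
#' with no qualifying day are excluded.
#'
#' @param dayStats data.frame with `day`, `uptimeMin`, `therapyMin`.
#' @param maxDay,minUptimeMin,minTherapyMin Inclusion thresholds.
#' @return List with `chosenDay` (NA if excluded), `excluded` flag, and the
#'   per-day `dayStats` examined.
#' @examples
#' selectBaselineDay(data.frame(day = 1:2, uptimeMin = c(239, 300),
#'                              therapyMin = c(20, 20)))$chosenDay  # 2
#' @export
selectBaselineDay <- function(dayStats, maxDay = 3L, minUptimeMin = 240,
                              minTherapyMin = 15) {
  if (!nrow(dayStats)) stop("need at least one candidate day")
  cand <- dayStats[dayStats$day <= maxDay &
                     dayStats$uptimeMin >= minUptimeMin &
                     dayStats$therapyMin >= minTherapyMin, , drop = FALSE]
  if (!nrow(cand))
    return(list(chosenDay = NA_integer_, excluded = TRUE,
                dayStats = dayStats))
  list(chosenDay = as.integer(min(cand$day)), excluded = FALSE,
       dayStats = dayStats)
}

#' Time spent as a percentage of uptime
#'
#' @param minutes Minutes in the state/location (`0 <= minutes <= uptime`).
#' @param uptime Denominator minutes, > 0.
#' @return `100 * minutes / uptime`.
#' @export
timePercent <- function(minutes, uptime) {
  if (any(uptime <= 0))
    stop("uptime must be > 0 (day should have been excluded upstream)")
  100 * minutes / uptime
}

#' Energy contributed by one window
#'
#' Per-window activity energy: the MAD on the cm/s^2 scale times the
#' window's time credit in minutes. Additive over windows and homogeneous in
#' the MAD.
#'
#' @param madCm Window MAD in cm/s^2.
#' @param minutes Time credit of the window in minutes (stride / 60).
#' @return Energy in cm/s^2 x min units.
#' @export
windowEnergy <- function(madCm, minutes) {
  madCm * minutes
}

#' Energy intensity of a state or location
#'
#' Total energy accumulated in a state/location divided by the minutes spent
#' in that same state/location (a per-minute intensity). States that never
#' occur have no defined intensity and are reported as `NA` (absent), not 0.
#'
#' @param energy Total energy in the state/location.
#' @param minutes Minutes in the same state/location.
#' @return Intensity per minute, or `NA` when `minutes == 0`.
#' @export
energyIntensity <- function(energy, minutes) {
  ifelse(minutes > 0, energy / minutes, NA_real_)
}

#' Energy share of a state
#'
#' @param stateEnergy Energy in the state.
#' @param totalEnergy Total daily energy, > 0.
#' @return `100 * stateEnergy / totalEnergy`.
#' @export
energyPercent <- function(stateEnergy, totalEnergy) {
  if (any(totalEnergy <= 0)) stop("total daily energy must be > 0")
  100 * stateEnergy / totalEnergy
}

#' Light vs moderate-to-vigorous intensity band
#'
#' Dichotomizes a per-minute energy intensity at the suggested cutoff of 90:
#' below is light, at or above is moderate-to-vigorous.
#'
#' @param intensity Non-negative intensity value(s).
#' @param cutoff Band boundary (default 90); the boundary itself belongs to
#'   the upper band.
#' @return Character vector: `"light"` or `"moderate_to_vigorous"`.
#' @examples
#' intensityBand(c(59, 90, 120))
#' @export
intensityBand <- function(intensity, cutoff = 90) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  ifelse(intensity < cutoff, "light", "moderate_to_vigorous")
}

#' Normalized feature vector for one patient-day
#'
#' Computes the per-day feature taxonomy from labeled, localized windows:
#' for each activity state (active, walking, standing, sitting, laying) the
#' time percentage, energy intensity and energy percentage; for each
#' canonical location and each room the time percentage and energy
#' intensity; plus total energy intensity and the raw energy components the
#' accounting identities are audited on. Time percentages use the
#' window-covered minutes as denominator so the exclusive
#' walking/standing/sitting/laying partition sums to exactly 100; windows
#' with unknown location contribute to state features but to no location
#' feature.
#'
#' @param windows data.frame with one row per window: `madCm`, `state`
#'   (walking/standing/sitting/laying), `motionState`, `canonicalLocation`,
#'   `room`.
#' @param strideSec Window time credit in seconds (the stride).
#' @param uptimeMin Wear-mask uptime in minutes (reported as-is).
#' @param locations Canonical location vocabulary defining the location
#'   columns (absent locations yield `NA` intensities and 0 time).
#' @return One-row data.frame of features.
#' @export
patientDayFeatures <- function(windows, strideSec = 9, uptimeMin = NA_real_,
                               locations = NULL) {
  stopifnot(nrow(windows) > 0)
  wmin <- strideSec / 60
  nW <- nrow(windows)
  totalMin <- nW * wmin
  energy <- windowEnergy(windows$madCm, wmin)
  totalEnergy <- sum(energy)
  out <- data.frame(uptime_min = uptimeMin, windowed_min = totalMin,
                    total_energy = totalEnergy,
                    total_ei = totalEnergy / totalMin)
  grab <- function(mask, tag) {
    mins <- sum(mask) * wmin
    e <- sum(energy[mask])
    res <- data.frame(timePercent(mins, totalMin), energyIntensity(e, mins),
                      e)
    names(res) <- paste0(c("time_pct_", "ei_", "e_"), tag)
    res
  }
  for (s in .ACTIVITY_STATES)
    out <- cbind(out, grab(windows$state == s, s))
  out <- cbind(out, grab(windows$motionState == "active", "active"))
  ## energy percentages: exclusive states + the active overlay
  if (totalEnergy > 0) {
    for (s in c(.ACTIVITY_STATES, "active")) {
      mask <- if (s == "active") windows$motionState == "active"
        else windows$state == s
      out[[paste0("epct_", s)]] <- energyPercent(sum(energy[mask]),
                                                 totalEnergy)
    }
  } else {
    for (s in c(.ACTIVITY_STATES, "active"))
      out[[paste0("epct_", s)]] <- NA_real_
  }
  if (is.null(locations))
    locations <- sort(setdiff(unique(windows$canonicalLocation), "unknown"))
  for (l in locations)
    out <- cbind(out, grab(windows$canonicalLocation == l,
                           paste0("loc_", l)))
  for (r in c("resident", "therapy"))
    out <- cbind(out, grab(windows$room == r, paste0(r, "_room")))
  out$e_unknown <- sum(energy[windows$room == "unknown"])
  out
}

#' Build the cohort feature table
#'
#' Applies the inclusion criteria and baseline-day selection per patient and
#' assembles one normalized feature row per included patient. Therapy-room
#' wear minutes per day are measured from the localized windows; uptime from
#' the wear mask (supplied via `metadata`).
#'
#' @param windows data.frame of labeled, localized windows across the
#'   cohort: `patientId`, `day`, `madCm`, `state`, `motionState`,
#'   `canonicalLocation`, `room`.
#' @param metadata data.frame with `patientId`, `day`, `outcome`,
#'   `uptimeMin`.
#' @param strideSec Window time credit (s).
#' @param maxDay,minUptimeMin,minTherapyMin Inclusion thresholds (first 3
#'   days, >= 240 min wear, >= 15 min therapy wear).
#' @param locations Canonical location vocabulary (defaults to the locations
#'   observed anywhere in `windows`).
#' @return data.frame, one row per included patient (`patientId`, `outcome`,
#'   `baselineDay`, features); excluded patient ids in
#'   `attr(, "excluded")`.
#' @export
buildFeatureTable <- function(windows, metadata, strideSec = 9,
                              maxDay = 3L, minUptimeMin = 240,
                              minTherapyMin = 15, locations = NULL) {
  wmin <- strideSec / 60
  if (is.null(locations))
    locations <- sort(setdiff(unique(windows$canonicalLocation), "unknown"))
  rows <- list(); excluded <- character(0)
  for (pid in unique(metadata$patientId)) {
    mdp <- metadata[metadata$patientId == pid, , drop = FALSE]
    dayStats <- do.call(rbind, lapply(seq_len(nrow(mdp)), function(i) {
      wd <- windows[windows$patientId == pid & windows$day == mdp$day[i], ,
                    drop = FALSE]
      data.frame(day = mdp$day[i], uptimeMin = mdp$uptimeMin[i],
                 therapyMin = sum(wd$room == "therapy") * wmin)
    }))
    sel <- selectBaselineDay(dayStats, maxDay, minUptimeMin, minTherapyMin)
    if (sel$excluded) {
      excluded <- c(excluded, pid)
      next
    }
    wd <- windows[windows$patientId == pid & windows$day == sel$chosenDay, ,
                  drop = FALSE]
    ft <- patientDayFeatures(
      wd, strideSec = strideSec,
      uptimeMin = mdp$uptimeMin[match(sel$chosenDay, mdp$day)],
      locations = locations)
    rows[[pid]] <- cbind(data.frame(patientId = pid,
                                    outcome = mdp$outcome[1],
                                    baselineDay = sel$chosenDay), ft)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patientId = character(0), outcome = character(0),
                      baselineDay = integer(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
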