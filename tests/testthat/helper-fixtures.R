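# Shared fixtures: everything is generated in code at test time.

# short-day config for cheap unit tests (90-min protocol day, full wear)
shortDayConfig <- function(..., dayEnd = 10.5 * 3600) {
  cohortConfig(nCommunity = 1L, nHospital = 0L, dropoutProb = 0,
               gapProb = 0, dayStart = 9 * 3600, dayEnd = dayEnd, ...)
}

# a hand-built schedule with explicit segments (full wear over their span)
manualSchedule <- function(segments, outcome = "community",
                           params = list(residentIntensity = 43)) {
  new("ProtocolSchedule", patientId = "PX", dayIndex = 1L,
      outcome = outcome, segments = segments,
      wearMask = data.frame(start = min(segments$start),
                            end = max(segments$end)),
      params = params)
}

oneSegment <- function(durationSec = 600, location = "resident_bed1",
                       posture = "lay", motion = "idle", start = 9 * 3600) {
  data.frame(start = start, end = start + durationSec, location = location,
             posture = posture, motion = motion)
}

# sinusoidal test signal sampled at fs
sineSeries <- function(freq, n, fs = 16, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# two-group feature draw with a programmed standardized difference
drawTwoGroups <- function(nC, nH, delta, sd = 1) {
  list(community = rnorm(nC, 0, sd), hospital = rnorm(nH, -delta * sd, sd))
}
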