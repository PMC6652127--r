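#' @include AllClasses.R
NULL

#' Signal magnitude of a triaxial acceleration series
#'
#' Per-sample Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` of the three axes,
#' gravity included, in g units.
#'
#' @param ax,ay,az Equal-length numeric vectors in g.
#' @return Non-negative numeric vector in g.
#' @examples
#' computeSignalMagnitude(0.6, 0.8, 0)  # 1
#' @export
computeSignalMagnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ax) != length(az))
    stop("axis series must have equal length")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Analytic Butterworth band-pass magnitude response
#'
#' `|H(f)| = 1 / sqrt(1 + W(f)^(2n))` with
#' `W(f) = (f^2 - low*high) / (f * (high - low))`, the standard low-pass to
#' band-pass transform of an order-`n` Butterworth prototype. Gain is 0 at
#' DC, 1 at the geometric mid-band and exactly -3.01 dB at both cut-offs.
#'
#' @param f Frequencies in Hz (>= 0).
#' @param spec A [FilterSpec-class].
#' @return Magnitude gains in `[0, 1]`.
#' @export
butterworthGain <- function(f, spec) {
  stopifnot(is(spec, "FilterSpec"))
  w <- ifelse(f > 0,
              (f^2 - spec@low * spec@high) / (f * (spec@high - spec@low)),
              Inf)
  g <- 1 / sqrt(1 + w^(2 * spec@order))
  g[f == 0] <- 0
  g
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the order-5 (configurable) Butterworth band-pass magnitude
#' response in the frequency domain: the series is transformed with the FFT,
#' each bin is scaled by [butterworthGain()], and the result is inverted.
#' This realization is zero-phase, removes the DC component exactly, and is
#' well defined when the upper cut-off sits at the Nyquist frequency -- as it
#' does for the 0.5--8 Hz band at 16 Hz sampling.
#'
#' @param x Numeric series (e.g. signal magnitude in m/s^2).
#' @param spec A [FilterSpec-class]; its `sampleRate` must match the data.
#' @return Filtered numeric series of the same length.
#' @examples
#' sp <- filterSpec()
#' t <- seq(0, 10 - 1 / 16, by = 1 / 16)
#' round(max(abs(bandpassFilter(rep(5, 160), sp))), 10)  # DC rejected
#' @export
bandpassFilter <- function(x, spec) {
  validObject(spec)
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * spec@sampleRate / n
  gain <- butterworthGain(f, spec)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Segment a stream into overlapping analysis windows
#'
#' Windows are `windowSec` long (160 samples at 16 Hz) and consecutive
#' windows share `overlapSec` of signal, i.e. the stride is
#' `windowSec - overlapSec` (9 s). Windows are anchored to contiguous wear
#' segments: a gap in the timestamps (missing samples) is never bridged, and
#' trailing partial windows are discarded.
#'
#' @param stream An [AccelStream-class], or a numeric timestamp vector.
#' @param windowSec,overlapSec Window length and overlap in seconds.
#' @param sampleRate Sampling rate in Hz.
#' @return data.frame with one row per window: `startIndex`, `startTime`,
#'   `n` (samples per window).
#' @examples
#' st <- accelStream(seq(0, 20, by = 1 / 16), 0, 0, 1)
#' nrow(segmentWindows(st))  # 2 windows: starts at 0 s and 9 s
#' @export
segmentWindows <- function(stream, windowSec = 10, overlapSec = 1,
                           sampleRate = 16) {
  time <- if (is(stream, "AccelStream")) stream@time else as.numeric(stream)
  nwin <- as.integer(round(windowSec * sampleRate))
  stride <- as.integer(round((windowSec - overlapSec) * sampleRate))
  if (stride < 1L || overlapSec >= windowSec)
    stop("overlap must be shorter than the window")
  out <- data.frame(startIndex = integer(0), startTime = numeric(0),
                    n = integer(0))
  if (length(time) < nwin) return(out)
  ## contiguous runs: break where spacing exceeds 1.5 sample intervals
  gap <- which(diff(time) > 1.5 / sampleRate)
  runStart <- c(1L, gap + 1L)
  runEnd <- c(gap, length(time))
  starts <- integer(0)
  for (r in seq_along(runStart)) {
    len <- runEnd[r] - runStart[r] + 1L
    if (len < nwin) next
    starts <- c(starts, seq(runStart[r], runStart[r] + len - nwin,
                            by = stride))
  }
  data.frame(startIndex = starts, startTime = time[starts],
             n = rep(nwin, length(starts)))
}

#' Mean absolute deviation of a window
#'
#' `(1/n) * sum(|x_i - mean(x)|)`: the per-window activity-energy proxy,
#' computed on the filtered signal magnitude in m/s^2.
#'
#' @param x Non-empty numeric window.
#' @return Non-negative scalar in the units of `x`.
#' @examples
#' computeMad(rep(c(-1, 1), 10))  # 1
#' @export
computeMad <- function(x) {
  if (!length(x)) stop("cannot compute MAD of an empty window")
  mean(abs(x - mean(x)))
}

#' Classify a window's motion state from its MAD
#'
#' Active if the MAD is greater than or equal to the threshold
#' (0.02 m/s^2 = 2 cm/s^2), otherwise idle; equality counts as active.
#'
#' @param mad Non-negative MAD value(s) in m/s^2.
#' @param threshold Decision threshold in m/s^2.
#' @return Character vector, `"active"` or `"idle"`.
#' @examples
#' classifyMotionState(c(0.02, 0.0199))
#' @export
classifyMotionState <- function(mad, threshold = 0.02) {
  if (any(!is.finite(mad)) || any(mad < 0))
    stop("mad must be finite and >= 0")
  ifelse(mad >= threshold, "active", "idle")
}

#' Displacement under constant acceleration from rest
#'
#' `s = a t^2 / 2` with zero initial velocity: the kinematic gloss of the
#' active/idle threshold (a constant 0.02 m/s^2 over a 10-s window moves the
#' wrist 1 m).
#'
#' @param a Constant acceleration in m/s^2 (>= 0).
#' @param t Duration in seconds (>= 0).
#' @return Displacement in metres.
#' @examples
#' displacementFromAcceleration(0.02, 10)  # 1
#' @export
displacementFromAcceleration <- function(a, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (any(a < 0)) stop("a must be >= 0")
  0.5 * a * t^2
}

#' Process an accelerometer stream into per-window records
#'
#' The full signal chain: signal magnitude (g), conversion to m/s^2
#' (1 g = 9.81 m/s^2), per-window zero-phase Butterworth band-pass filtering
#' of 160-sample batches, MAD, active/idle state, and the 7 window features
#' used by the activity-recognition hierarchy.
#'
#' @param stream An [AccelStream-class].
#' @param spec A [FilterSpec-class].
#' @param windowSec,overlapSec Windowing parameters in seconds.
#' @param madThreshold Active/idle threshold in m/s^2.
#' @param features Also compute the 7 window features (default `TRUE`).
#' @return data.frame with one row per window: provenance, `startTime`,
#'   `mad` (m/s^2), `madCm` (cm/s^2), `motionState`, and feature columns.
#' @export
processAccelStream <- function(stream, spec = filterSpec(),
                               windowSec = 10, overlapSec = 1,
                               madThreshold = 0.02, features = TRUE) {
  stopifnot(is(stream, "AccelStream"))
  win <- segmentWindows(stream, windowSec, overlapSec, spec@sampleRate)
  if (!nrow(win)) {
    out <- data.frame(patientId = character(0), day = integer(0),
                      startTime = numeric(0), mad = numeric(0),
                      madCm = numeric(0), motionState = character(0))
    return(out)
  }
  sm <- gToMs2(computeSignalMagnitude(stream@ax, stream@ay, stream@az))
  nwin <- win$n[1]
  idx <- outer(0:(nwin - 1L), win$startIndex, `+`)  # nwin x nWindows
  mat <- matrix(sm[idx], nrow = nwin)
  filt <- apply(mat, 2L, bandpassFilter, spec = spec)
  mad <- apply(filt, 2L, computeMad)
  out <- data.frame(patientId = stream@patientId, day = stream@dayIndex,
                    startTime = win$startTime, mad = mad, madCm = 100 * mad,
                    motionState = classifyMotionState(mad, madThreshold))
  if (features)
    out <- cbind(out, windowFeatureTable(filt, spec@sampleRate))
  out
}
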