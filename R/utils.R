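## Shared constants and small helpers.

## Standard gravity used at the g -> SI conversion boundary (1 g = 9.81 m/s^2).
.GRAVITY_MS2 <- 9.81

#' Convert acceleration from g units to metres per second squared
#'
#' The conversion constant is fixed at 1 g = 9.81 m/s^2; every SI-unit
#' quantity in the package (filtered magnitude, MAD, the 0.02 m/s^2
#' active/idle threshold) goes through this single boundary.
#'
#' @param g Numeric vector of accelerations in g units.
#' @return Numeric vector in m/s^2.
#' @examples
#' gToMs2(1)      # 9.81
#' gToMs2(c(0, 2))
#' @export
gToMs2 <- function(g) {
  stopifnot(is.numeric(g))
  g * .GRAVITY_MS2
}

## one foot in metres; path-loss reference distance
.FOOT_M <- 0.3048

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

## seconds-since-midnight pretty printer for show() methods
.fmtClock <- function(s) {
  h <- floor(s / 3600); m <- floor((s - h * 3600) / 60)
  sprintf("%02d:%02d", as.integer(h), as.integer(m))
}
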