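#' Low-precision solar ephemeris (declination and equation of time)
#'
#' Computes the solar declination and the equation of time for a vector of UTC
#' instants, using the NOAA low-precision algorithm (fractional-year Fourier
#' expansion; accuracy about 0.2 degrees in declination, well inside what the
#' threshold method needs). These two quantities are all the astronomy that
#' light-level geolocation requires: longitude follows from the timing of local
#' solar noon/midnight via the equation of time, latitude from day length via
#' the sunrise equation.
#'
#' @param time `POSIXct` vector (interpreted in UTC).
#' @return A tibble with columns `time`, `declination` (degrees, positive
#'   north; |declination| <= 23.45) and `eqtime` (equation of time, minutes of
#'   time, apparent minus mean solar time; |eqtime| <= 17).
#' @examples
#' solar_state(as.POSIXct("2009-06-21 12:00:00", tz = "UTC"))
#' @export
solar_state <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  if (any(yr < 1990 | yr > 2100)) {
    stop("solar_state() is validated for years 1990-2100 only", call. = FALSE)
  }
  lt <- as.POSIXlt(time, tz = "UTC")
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (lt$yday + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) * 180 / pi
  tibble::tibble(time = time, declination = decl, eqtime = eqtime)
}

#' Solar elevation above the horizon
#'
#' Elevation of the sun's centre for given UTC instants and positions, from the
#' same low-precision ephemeris as [solar_state()]. No atmospheric refraction
#' is applied: light-transfer calibration absorbs any constant offset.
#'
#' @param time `POSIXct` vector (UTC).
#' @param lat,lon position in decimal degrees (north/east positive). Recycled
#'   against `time`.
#' @return Numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  s <- solar_state(time)
  lt <- as.POSIXlt(time, tz = "UTC")
  tst <- (lt$hour * 60 + lt$min + lt$sec / 60) + s$eqtime + 4 * lon
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  decr <- s$declination * pi / 180
  sinel <- sin(latr) * sin(decr) + cos(latr) * cos(decr) * cos(ha)
  asin(pmin(1, pmax(-1, sinel))) * 180 / pi
}
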