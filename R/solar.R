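# Solar geometry from the standard NOAA low-precision equations: adequate to
# well under a minute for dusk times at mid-latitudes, which is far below the
# one-hour resolution of the camera-hour analysis.

.deg2rad <- function(d) d * pi / 180

# fractional year (radians) at local noon of a Date
.fracYear <- function(date) {
  yday <- as.POSIXlt(date)$yday
  2 * pi / 365 * (yday + 0.5)
}

# equation of time (minutes) and solar declination (radians)
.solarParams <- function(date) {
  g <- .fracYear(date)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

# UTC decimal hour at which the sun crosses `altitude` degrees, setting side
.sunCrossUTC <- function(date, lat, lon, altitude) {
  p <- .solarParams(date)
  phi <- .deg2rad(lat)
  h0 <- .deg2rad(altitude)
  cosw <- (sin(h0) - sin(phi) * sin(p$decl)) / (cos(phi) * cos(p$decl))
  if (any(cosw < -1 | cosw > 1))
    stop("sun never crosses the requested altitude at this latitude/date")
  w <- acos(cosw) * 180 / pi          # degrees
  solarNoonUTC <- 12 - lon / 15 - p$eqtime / 60
  solarNoonUTC + w / 15
}

#' Civil dusk time
#'
#' Time at which the sun reaches 6 degrees below the horizon on the evening
#' of `date`, at a point given in geographic coordinates.
#'
#' @param date a Date (or coercible).
#' @param lat,lon latitude/longitude in degrees (east positive).
#' @return POSIXct (UTC) dusk instant.
#' @examples
#' duskTime(as.Date("2012-06-21"), lat = 41.88, lon = 0)
#' @export
duskTime <- function(date, lat, lon = 0) {
  date <- as.Date(date)
  h <- .sunCrossUTC(date, lat, lon, -6)
  as.POSIXct(date, tz = "UTC") + h * 3600
}

#' Day length in hours
#'
#' Sunrise-to-sunset duration using the conventional -0.833 degree solar
#' altitude (refraction + solar radius).
#'
#' @inheritParams duskTime
#' @return day length (hours).
#' @export
dayLength <- function(date, lat) {
  p <- .solarParams(as.Date(date))
  phi <- .deg2rad(lat)
  h0 <- .deg2rad(-0.833)
  cosw <- (sin(h0) - sin(phi) * sin(p$decl)) / (cos(phi) * cos(p$decl))
  cosw <- pmin(pmax(cosw, -1), 1)
  2 * acos(cosw) * 180 / pi / 15
}

#' Fraction of the moon illuminated
#'
#' Mean-synodic-cycle approximation: phase age measured from a reference new
#' moon (2000-01-06 18:14 UTC), illuminated fraction
#' (1 - cos(2 pi age / 29.53)) / 2.  A smooth proxy covariate, not an
#' ephemeris.
#'
#' @param time POSIXct vector.
#' @return illuminated fraction in \[0, 1\].
#' @export
moonFraction <- function(time) {
  ref <- as.POSIXct("2000-01-06 18:14:00", tz = "UTC")
  age <- as.numeric(difftime(time, ref, units = "days")) %% 29.530588
  (1 - cos(2 * pi * age / 29.530588)) / 2
}
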