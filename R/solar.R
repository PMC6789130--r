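# Low-precision solar ephemeris (NOAA-style polynomial series).
# Accuracy ~0.01 deg in declination and a few seconds in the equation of
# time -- far below threshold-geolocation error. Elevations are geometric
# (no refraction); the calibrated sun elevation angle absorbs refraction.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Solar declination and equation of time
#'
#' Computes the apparent solar declination and the equation of time for one
#' or more instants, using the NOAA polynomial series in Julian centuries
#' from J2000.
#'
#' @param time a `POSIXct` vector (UTC).
#' @return A list with components `declination` (degrees) and `eot`
#'   (equation of time, minutes; apparent solar time minus mean solar time).
#' @examples
#' s <- solar_position(as.POSIXct("2012-06-21 12:00:00", tz = "UTC"))
#' s$declination  # ~ +23.44 near the June solstice
#' @export
solar_position <- function(time) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525

  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m  <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)

  mr <- .deg2rad(m)
  c <- sin(mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * mr) * (0.019993 - 0.000101 * t) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(.deg2rad(omega))

  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - 0.001813 * t))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(.deg2rad(omega))
  epsr <- .deg2rad(eps)

  decl <- asin(sin(epsr) * sin(.deg2rad(app_long)))

  y <- tan(epsr / 2)^2
  l0r <- .deg2rad(l0)
  eot <- 4 * .rad2deg(
    y * sin(2 * l0r) - 2 * ecc * sin(mr) +
      4 * ecc * y * sin(mr) * cos(2 * l0r) -
      0.5 * y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * mr)
  )

  list(declination = .rad2deg(decl), eot = eot)
}

#' Solar elevation angle
#'
#' Geometric solar elevation above the horizon at given positions and times.
#'
#' @param time `POSIXct` vector (UTC).
#' @param lon,lat position in decimal degrees (recycled against `time`).
#' @return Elevation in degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  sp <- solar_position(time)
  mins <- (as.numeric(time) %% 86400) / 60
  tst <- (mins + sp$eot + 4 * lon) %% 1440
  ha <- .deg2rad(tst / 4 - 180)
  phi <- .deg2rad(lat)
  decl <- .deg2rad(sp$declination)
  .rad2deg(asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)))
}

#' Equinox dates of a calendar year
#'
#' Locates the two zero crossings of solar declination (March and September
#' equinoxes) by root finding on the ephemeris, rather than from a fixed
#' table.
#'
#' @param year integer calendar year.
#' @return A `Date` vector of length 2 (March, September), the civil UTC
#'   dates containing the crossings.
#' @export
equinox_dates <- function(year) {
  decl_at <- function(day_frac, origin) {
    solar_position(origin + day_frac * 86400)$declination
  }
  mar0 <- as.POSIXct(sprintf("%d-03-15 00:00:00", year), tz = "UTC")
  sep0 <- as.POSIXct(sprintf("%d-09-15 00:00:00", year), tz = "UTC")
  rmar <- stats::uniroot(decl_at, c(0, 12), origin = mar0)$root
  rsep <- stats::uniroot(decl_at, c(0, 12), origin = sep0)$root
  as.Date(c(mar0 + rmar * 86400, sep0 + rsep * 86400))
}

#' Twilight times for a date and position
#'
#' Solves for the UTC times at which the sun crosses a given elevation angle
#' on a civil date at a fixed position, iterating the hour-angle equation
#' with the declination and equation of time refreshed at the event time.
#'
#' @param date a `Date` vector.
#' @param lon,lat position in decimal degrees.
#' @param ea sun elevation angle defining the event (degrees, typically
#'   negative).
#' @return A data.frame with columns `date`, `sunrise`, `sunset` (`POSIXct`
#'   UTC; `NA` for polar day/night).
#' @export
twilight_times <- function(date, lon, lat, ea = -6) {
  noon_guess <- as.POSIXct(as.character(date), tz = "UTC") + 12 * 3600
  sr <- ss <- noon_guess
  for (i in 1:3) {
    # sunrise pass
    sp <- solar_position(sr)
    cosh0 <- (sin(.deg2rad(ea)) - sin(.deg2rad(lat)) * sin(.deg2rad(sp$declination))) /
      (cos(.deg2rad(lat)) * cos(.deg2rad(sp$declination)))
    h0 <- suppressWarnings(.rad2deg(acos(pmin(1, pmax(-1, cosh0)))))
    h0[abs(cosh0) > 1] <- NA
    noon_min <- 720 - 4 * lon - sp$eot
    sr <- as.POSIXct(as.character(date), tz = "UTC") + (noon_min - 4 * h0) * 60
    # sunset pass
    sp2 <- solar_position(ss)
    cosh02 <- (sin(.deg2rad(ea)) - sin(.deg2rad(lat)) * sin(.deg2rad(sp2$declination))) /
      (cos(.deg2rad(lat)) * cos(.deg2rad(sp2$declination)))
    h02 <- suppressWarnings(.rad2deg(acos(pmin(1, pmax(-1, cosh02)))))
    h02[abs(cosh02) > 1] <- NA
    noon_min2 <- 720 - 4 * lon - sp2$eot
    ss <- as.POSIXct(as.character(date), tz = "UTC") + (noon_min2 + 4 * h02) * 60
  }
  data.frame(date = date, sunrise = sr, sunset = ss)
}

#' Night intervals at a colony
#'
#' Builds per-date night intervals (dusk of `date` to dawn of `date + 1`) at
#' a fixed location, for use by the immersion-based night-visit detector.
#' The night labelled with date d is the night beginning at dusk of d.
#'
#' @param dates `Date` vector of evening dates.
#' @param lon,lat colony position (degrees).
#' @param ea sun elevation angle defining dusk/dawn (default -6, civil
#'   twilight; colony attendance in burrow-nesters is crepuscular/nocturnal).
#' @return A data.frame with columns `date`, `dusk`, `dawn` (`POSIXct` UTC).
#' @export
night_intervals <- function(dates, lon, lat, ea = -6) {
  tw_d <- twilight_times(dates, lon, lat, ea = ea)
  tw_n <- twilight_times(dates + 1, lon, lat, ea = ea)
  data.frame(date = dates, dusk = tw_d$sunset, dawn = tw_n$sunrise)
}

#' Day intervals at a colony
#'
#' Per-date daylight intervals (dawn to dusk of the same civil date), for the
#' light-based day-visit detector.
#'
#' @inheritParams night_intervals
#' @return A data.frame with columns `date`, `dawn`, `dusk` (`POSIXct` UTC).
#' @export
day_intervals <- function(dates, lon, lat, ea = -6) {
  tw <- twilight_times(dates, lon, lat, ea = ea)
  data.frame(date = dates, dawn = tw$sunrise, dusk = tw$sunset)
}
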