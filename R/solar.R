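# Low-precision solar geometry (Spencer's Fourier fits, as used in the NOAA
# solar calculator).  Accuracy ~0.2-0.3 degrees in declination and ~1 min in
# the equation of time, ample for threshold geolocation where positional
# noise is one to two orders of magnitude larger.

#' Solar declination and equation of time
#'
#' @param time A `Date` or UTC `POSIXct` vector within the years 1900-2100.
#'   `Date` inputs are evaluated at 12:00 UTC.
#' @return A data frame with `declination` (degrees, within +/- 23.45) and
#'   `eq_time` (minutes, apparent minus mean solar time, within +/- 17).
#' @export
#' @examples
#' solar_ephemeris(as.Date("2020-06-21"))$declination  # ~23.4
solar_ephemeris <- function(time) {
  t <- if (inherits(time, "Date")) {
    as.POSIXct(paste(format(time), "12:00:00"), tz = "UTC")
  } else {
    as.POSIXct(time, tz = "UTC")
  }
  yr <- as.integer(format(t, "%Y"))
  if (any(yr < 1900 | yr > 2100)) stop("time outside supported years 1900-2100")
  doy <- as.integer(format(t, "%j"))
  hod <- as.numeric(t - as.POSIXct(paste(format(t, "%Y-%m-%d"), "00:00:00"),
                                   tz = "UTC"), units = "hours")
  g <- 2 * pi / 365 * (doy - 1 + (hod - 12) / 24)
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
             0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
             0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) * 180 / pi
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  data.frame(declination = decl, eq_time = eqt)
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon for a site and UTC time, from the
#' low-precision ephemeris.
#'
#' @param time UTC `POSIXct` vector.
#' @param lat,lon Site coordinates in decimal degrees.
#' @return Elevation in degrees (negative below the horizon).
#' @export
solar_elevation <- function(time, lat, lon) {
  eph <- solar_ephemeris(time)
  t <- as.POSIXct(time, tz = "UTC")
  utc_min <- as.numeric(t - as.POSIXct(paste(format(t, "%Y-%m-%d"), "00:00:00"),
                                       tz = "UTC"), units = "mins")
  tst <- utc_min + eph$eq_time + 4 * lon      # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180            # hour angle, radians
  phi <- lat * pi / 180
  dec <- eph$declination * pi / 180
  asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha)) * 180 / pi
}
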