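# Synthetic geolocator light series: the inverse problem for threshold
# geolocation.  Light is an idealised step function of solar elevation; no
# cloud shading, sensor saturation curves or topography are emulated.

#' Simulate an archival light-logger series for a stationary site
#'
#' Emits a regularly sampled light series that is high whenever the sun is
#' above the elevation implied by `zenith` and low otherwise.  Continuous
#' light (polar day) and continuous dark days come out as all-high / all-low
#' and so produce no twilight events downstream.
#'
#' @param lat,lon Site coordinates in decimal degrees.
#' @param start_date,end_date First and last calendar day (`Date` or string).
#' @param interval_min Sampling interval in minutes; must be <= 10.
#' @param zenith Sun zenith angle defining the light threshold, degrees in
#'   [90, 96].  The default 93 matches a typical GLS threshold calibration.
#' @param light_high,light_low Sensor values emitted above/below threshold.
#' @return Data frame with `timestamp_utc` (POSIXct) and `light`.
#' @export
#' @examples
#' ls <- simulate_light_series(0, 0, "2020-03-20", "2020-03-20")
#' range(ls$light)
simulate_light_series <- function(lat, lon, start_date, end_date,
                                  interval_min = 2, zenith = 93,
                                  light_high = 64, light_low = 0) {
  if (interval_min > 10) stop("sampling_interval must be <= 10 minutes")
  if (zenith < 90 || zenith > 96) stop("zenith_angle must be in [90, 96]")
  times <- seq(as.POSIXct(paste(format(as.Date(start_date)), "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(format(as.Date(end_date)), "23:59:59"), tz = "UTC"),
               by = interval_min * 60)
  elev <- solar_elevation(times, lat, lon)
  data.frame(timestamp_utc = times,
             light = ifelse(elev > 90 - zenith, light_high, light_low))
}

#' Write / read a light series CSV
#'
#' Plain CSV with columns `timestamp_utc` (ISO 8601, UTC) and `light`.
#' @param light Data frame as returned by [simulate_light_series()].
#' @param path File path.
#' @return `read_light_series` returns the data frame with POSIXct timestamps.
#' @export
write_light_series <- function(light, path) {
  out <- data.frame(
    timestamp_utc = format(light$timestamp_utc, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    light = light$light)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_light_series
#' @export
read_light_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp_utc <- as.POSIXct(x$timestamp_utc, format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
  x
}
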