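# Threshold-method geolocation: longitude from the timing of solar noon (or
# solar midnight), latitude from day length via the sunrise equation.
# Near the equinoxes day length is ~12 h at every latitude, so latitude is
# unidentifiable from light data; such days are flagged rather than guessed.

#' Geolocation configuration
#'
#' @param zenith Sun zenith angle at the calibrated light threshold, degrees
#'   in [90, 96].  93 is a civil-twilight-like value typical of GLS
#'   threshold calibrations; site-specific calibration can be supplied here.
#' @param threshold Light level defining a twilight crossing, in sensor units.
#' @param equinox_window Half-width, in days, of the calendar window around
#'   Mar 20 and Sep 22 within which latitudes are treated as unknown.
#' @return A list of class `geolocation_config`.
#' @export
geolocation_config <- function(zenith = 93, threshold = 32,
                               equinox_window = 10) {
  if (zenith < 90 || zenith > 96) stop("zenith must be in [90, 96]")
  if (equinox_window < 0) stop("equinox_window must be >= 0")
  structure(list(zenith = zenith, threshold = threshold,
                 equinox_window = equinox_window),
            class = "geolocation_config")
}

# Declination magnitude below which day length carries essentially no
# latitude information, implied by a calendar window of W days around the
# equinox (declination moves ~ 23.44 * sin(2*pi*W/365.24) in W days).
equinox_declination_cutoff <- function(equinox_window) {
  23.44 * abs(sin(2 * pi * equinox_window / 365.2422))
}

#' Detect twilight events by threshold crossing
#'
#' One sunrise per upward crossing of the light threshold and one sunset per
#' downward crossing, with the crossing time linearly interpolated between
#' the bracketing samples.  All-high or all-low stretches yield no events.
#'
#' @param light Data frame with `timestamp_utc` (POSIXct) and `light`.
#' @param config A [geolocation_config()].
#' @return Data frame with `timestamp` (POSIXct) and `kind`
#'   (`"sunrise"`/`"sunset"`), in time order.
#' @export
detect_twilights <- function(light, config = geolocation_config()) {
  if (nrow(light) == 0L) stop("empty light series")
  if (is.unsorted(light$timestamp_utc, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  l <- light$light
  t <- as.numeric(light$timestamp_utc)
  thr <- config$threshold
  n <- length(l)
  lo <- l[-n] < thr & l[-1] >= thr
  hi <- l[-n] >= thr & l[-1] < thr
  cross <- function(i) {
    frac <- (thr - l[i]) / (l[i + 1] - l[i])
    t[i] + frac * (t[i + 1] - t[i])
  }
  up <- which(lo); down <- which(hi)
  ev <- rbind(
    data.frame(timestamp = cross(up), kind = rep("sunrise", length(up))),
    data.frame(timestamp = cross(down), kind = rep("sunset", length(down))))
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ev$timestamp <- as.POSIXct(ev$timestamp, origin = "1970-01-01", tz = "UTC")
  rownames(ev) <- NULL
  ev
}

# Solve the sunrise equation cos(z0) = sin(phi) sin(delta) +
# cos(phi) cos(delta) cos(H) for latitude phi given the half-day hour angle
# H (degrees) and declination delta (degrees).  Returns NA when no solution
# exists (polar day/night for every candidate latitude).
latitude_from_daylength <- function(half_day_deg, declination, zenith) {
  a <- sin(declination * pi / 180)
  b <- cos(declination * pi / 180) * cos(half_day_deg * pi / 180)
  c0 <- cos(zenith * pi / 180)
  r0 <- sqrt(a^2 + b^2)
  s <- c0 / r0
  if (abs(s) > 1) return(NA_real_)
  psi <- atan2(b, a)
  cand <- c(asin(s) - psi, pi - asin(s) - psi)
  cand <- wrap_lon(cand * 180 / pi)   # fold into (-180, 180]
  cand <- cand[cand >= -90 - 1e-9 & cand <= 90 + 1e-9]
  if (length(cand) == 0L) return(NA_real_)
  # principal (equator-side) branch first; it is the physical one for
  # ordinary day lengths
  max(-90, min(90, cand[1]))
}

#' Position from a sunrise/sunset pair
#'
#' Longitude is 15 degrees per hour of offset between 12:00 UTC and solar
#' noon (the pair midpoint corrected by the equation of time); latitude
#' solves the sunrise equation from day length.  The latitude is marked
#' invalid when the solar declination is within the equinox dead zone
#' implied by `equinox_window`, or when the sunrise equation has no
#' solution.
#'
#' @param sunrise,sunset POSIXct twilight times; sunrise must precede sunset
#'   and both must fall within 24 h.
#' @param config A [geolocation_config()].
#' @return A one-row data frame: `lat`, `lon`, `lat_valid`.
#' @export
twilight_to_position <- function(sunrise, sunset,
                                 config = geolocation_config()) {
  if (sunset <= sunrise) stop("sunset before sunrise")
  if (as.numeric(sunset - sunrise, units = "hours") > 24) {
    stop("twilight pair spans more than 24 h")
  }
  mid <- sunrise + as.numeric(sunset - sunrise, units = "secs") / 2
  eph <- solar_ephemeris(mid)
  utc_min <- as.numeric(mid - as.POSIXct(paste(format(mid, "%Y-%m-%d"), "00:00:00"),
                                         tz = "UTC"), units = "mins")
  lon <- wrap_lon((720 - utc_min - eph$eq_time) / 4)
  day_h <- as.numeric(sunset - sunrise, units = "hours")
  lat <- latitude_from_daylength(day_h * 15 / 2, eph$declination, config$zenith)
  valid <- !is.na(lat) &&
    abs(eph$declination) >= equinox_declination_cutoff(config$equinox_window)
  data.frame(lat = ifelse(valid, lat, NA_real_), lon = lon, lat_valid = valid)
}

# Internal: a fix (lat/lon/validity + reference time) from two consecutive
# twilight events.  A sunrise->sunset pair measures the day directly; a
# sunset->sunrise pair measures the night, giving day length 24 h minus the
# gap and solar midnight at the gap midpoint.
fix_from_pair <- function(e1_time, e1_kind, e2_time, config) {
  gap_h <- as.numeric(e2_time - e1_time, units = "hours")
  mid <- e1_time + as.numeric(e2_time - e1_time, units = "secs") / 2
  eph <- solar_ephemeris(mid)
  utc_min <- as.numeric(mid - as.POSIXct(paste(format(mid, "%Y-%m-%d"), "00:00:00"),
                                         tz = "UTC"), units = "mins")
  if (e1_kind == "sunrise") {      # daytime pair: midpoint is solar noon
    lon <- wrap_lon((720 - utc_min - eph$eq_time) / 4)
    day_h <- gap_h
  } else {                         # nighttime pair: midpoint is solar midnight
    lon <- wrap_lon((1440 - utc_min - eph$eq_time) / 4)
    day_h <- 24 - gap_h
  }
  lat <- latitude_from_daylength(day_h * 15 / 2, eph$declination, config$zenith)
  valid <- !is.na(lat) &&
    abs(eph$declination) >= equinox_declination_cutoff(config$equinox_window)
  list(time = mid, lat = if (valid) lat else NA_real_, lon = lon,
       lat_valid = valid)
}

#' Average twilight fixes into daily positions
#'
#' Consecutive twilight events within 24 h of each other form fixes (a
#' day-side and a night-side fix per solar day).  Fixes are assigned to the
#' calendar day of their midpoint in local solar time (using the longitude
#' of the previous fix, falling back to UTC for the first), then averaged
#' into one position per day, with a circular mean for longitude.  Days
#' without a valid latitude fix carry `lat = NA`, `lat_valid = FALSE`.
#'
#' @param twilights Data frame from [detect_twilights()].
#' @param config A [geolocation_config()].
#' @return Data frame with `date`, `lat`, `lon`, `lat_valid`.
#' @export
daily_positions <- function(twilights, config = geolocation_config()) {
  n <- nrow(twilights)
  if (n < 2L) return(data.frame(date = as.Date(character()), lat = numeric(),
                                lon = numeric(), lat_valid = logical()))
  kinds <- twilights$kind
  if (any(kinds[-1] == kinds[-n])) stop("twilight kinds must alternate")
  fixes <- vector("list", n - 1L)
  prev_lon <- 0
  have_prev <- FALSE
  for (i in seq_len(n - 1L)) {
    if (as.numeric(twilights$timestamp[i + 1] - twilights$timestamp[i],
                   units = "hours") > 24) next
    fx <- fix_from_pair(twilights$timestamp[i], kinds[i],
                        twilights$timestamp[i + 1], config)
    ref_lon <- if (have_prev) prev_lon else 0
    fx$date <- as.Date(fx$time + ref_lon / 15 * 3600, tz = "UTC")
    fixes[[i]] <- fx
    prev_lon <- fx$lon
    have_prev <- TRUE
  }
  fixes <- fixes[!vapply(fixes, is.null, logical(1))]
  if (length(fixes) == 0L) {
    return(data.frame(date = as.Date(character()), lat = numeric(),
                      lon = numeric(), lat_valid = logical()))
  }
  fx <- data.frame(date = as.Date(vapply(fixes, function(f) as.character(f$date),
                                         character(1))),
                   lat = vapply(fixes, function(f) f$lat, numeric(1)),
                   lon = vapply(fixes, function(f) f$lon, numeric(1)),
                   lat_valid = vapply(fixes, function(f) f$lat_valid, logical(1)))
  out <- do.call(rbind, lapply(split(fx, fx$date), function(d) {
    lat <- if (any(d$lat_valid)) mean(d$lat[d$lat_valid]) else NA_real_
    data.frame(date = d$date[1], lat = lat,
               lon = circular_mean_lon(d$lon),
               lat_valid = any(d$lat_valid))
  }))
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

# Days to the nearest Mar 20 / Sep 22 (calendar convention for the equinox).
days_to_equinox <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  cand <- cbind(
    as.Date(paste0(yr - 1, "-09-22")),
    as.Date(paste0(yr, "-03-20")), as.Date(paste0(yr, "-09-22")),
    as.Date(paste0(yr + 1, "-03-20")))
  apply(abs(matrix(as.numeric(cand) - as.numeric(dates), nrow = length(dates))),
        1, min)
}

#' Flag equinox-affected latitudes in a track
#'
#' Forces `lat_valid = FALSE` (and `lat = NA`) for dates within `window`
#' days of Mar 20 or Sep 22; longitudes are untouched.
#'
#' @param track A track data frame with at least `date`, `lat`, `lat_valid`.
#' @param window Half-width of the flagging window in days (>= 0).
#' @return The track with flagged latitudes.
#' @export
flag_equinox <- function(track, window = 10) {
  if (window < 0) stop("window must be >= 0")
  hit <- days_to_equinox(track$date) <= window
  track$lat_valid <- track$lat_valid & !hit
  track$lat[hit] <- NA_real_
  track
}

#' Interpolate equinox-flagged latitudes
#'
#' Linear interpolation of latitude over invalid days between the flanking
#' valid fixes (constant extension at the track ends).  Longitudes are kept
#' as observed.  Adds a logical column `lat_interpolated`.
#'
#' @param track A per-bird track data frame (`date`, `lat`, `lon`,
#'   `lat_valid`).
#' @return The track with a complete latitude column.
#' @export
interpolate_equinox <- function(track) {
  track <- track[order(track$date), , drop = FALSE]
  ok <- track$lat_valid & !is.na(track$lat)
  if (!any(ok)) stop("all latitudes undefined; cannot interpolate")
  track$lat_interpolated <- !ok
  if (any(!ok)) {
    track$lat[!ok] <- stats::approx(as.numeric(track$date[ok]), track$lat[ok],
                                    xout = as.numeric(track$date[!ok]),
                                    rule = 2)$y
  }
  track
}

#' Geolocate a light series into a daily track
#'
#' Convenience wrapper: [detect_twilights()], [daily_positions()] and
#' [flag_equinox()] in sequence.
#'
#' @param light Light series data frame (`timestamp_utc`, `light`).
#' @param config A [geolocation_config()].
#' @param bird_id Identifier attached to the output.
#' @return A track data frame: `bird_id`, `date`, `lat`, `lon`, `lat_valid`.
#' @export
geolocate <- function(light, config = geolocation_config(), bird_id = "bird") {
  tw <- detect_twilights(light, config)
  pos <- daily_positions(tw, config)
  pos <- flag_equinox(pos, config$equinox_window)
  cbind(bird_id = bird_id, pos)
}
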