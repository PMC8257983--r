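# Tailwind annotation of travel steps: interpolate gridded winds at the
# step midpoint, decompose along the track azimuth, pick the pressure level
# with the strongest tailwind within the allowed altitude band, and report
# the International Standard Atmosphere (ISA) altitude of that level.

#' Pressure to ISA altitude
#'
#' Inverts the barometric formula of the International Standard Atmosphere
#' troposphere: `z = (T0/L) (1 - (p/p0)^(R L / g))` with T0 = 288.15 K,
#' L = 0.0065 K/m, p0 = 1013.25 hPa, R = 287.053 J/(kg K), g = 9.80665.
#'
#' @param p Pressure in hPa, in [10, 1100] (vectorised).
#' @return Altitude in metres above sea level.
#' @export
#' @examples
#' pressure_to_altitude(c(1013.25, 500))  # 0 m and ~5574 m
pressure_to_altitude <- function(p) {
  if (any(p <= 0)) stop("pressure must be positive")
  if (any(p < 10 | p > 1100)) stop("pressure must be in [10, 1100] hPa")
  T0 <- 288.15; L <- 0.0065; p0 <- 1013.25; R <- 287.053; g <- 9.80665
  (T0 / L) * (1 - (p / p0)^(R * L / g))
}

#' Tailwind / crosswind decomposition
#'
#' Projects the horizontal wind onto the track azimuth:
#' `Vt = u sin(a) + v cos(a)` (positive = wind pushes along the track) and
#' `Vc = u cos(a) - v sin(a)`; magnitude is preserved.
#'
#' @param u,v Wind components, m/s (vectorised).
#' @param azimuth Track azimuth, degrees clockwise from north in [0, 360).
#' @return Data frame with `tailwind` and `crosswind`, m/s.
#' @export
tailwind_component <- function(u, v, azimuth) {
  if (any(azimuth < 0 | azimuth >= 360)) stop("azimuth must be in [0, 360)")
  a <- azimuth * pi / 180
  data.frame(tailwind = u * sin(a) + v * cos(a),
             crosswind = u * cos(a) - v * sin(a))
}

#' Wind-annotation configuration
#'
#' @param levels Pressure levels to evaluate, hPa.
#' @param allowed_range Pressure range (hPa) a bird may select within,
#'   `c(low_pressure, high_pressure)` in any order; the default 500-1000
#'   hPa caps flight altitude near 5,500 m.
#' @param airspeed Assumed airspeed (m/s), used only to report the
#'   tailwind:airspeed ratio; it never affects level selection.
#' @return A list of class `wind_config`.
#' @export
wind_config <- function(levels = c(1000, 925, 850, 700, 600, 500),
                        allowed_range = c(1000, 500), airspeed = 10.6) {
  structure(list(levels = sort(levels, decreasing = TRUE),
                 allowed_range = sort(allowed_range), airspeed = airspeed),
            class = "wind_config")
}

#' Tailwind profile of a flight step
#'
#' Samples the wind at the step's spatial midpoint and 12:00 UTC of the
#' step date, for each pressure level, and decomposes it along the step
#' azimuth.  ISA altitude is attached per level.
#'
#' @param field A `wind_field`.
#' @param from_lat,from_lon,to_lat,to_lon Step endpoints, degrees.
#' @param date Step date (`Date`).
#' @param levels Pressure levels, hPa.
#' @return Data frame: `level`, `altitude`, `u`, `v`, `tailwind`,
#'   `crosswind`, ordered by decreasing pressure.
#' @export
tailwind_profile <- function(field, from_lat, from_lon, to_lat, to_lon, date,
                             levels = c(1000, 925, 850, 700, 600, 500)) {
  mid <- gc_midpoint(from_lat, from_lon, to_lat, to_lon)
  az <- initial_bearing(from_lat, from_lon, to_lat, to_lon)
  tm <- as.POSIXct(paste(format(as.Date(date)), "12:00:00"), tz = "UTC")
  levels <- sort(levels, decreasing = TRUE)
  w <- sample_wind(field, rep(mid[1, "lon"], length(levels)),
                   rep(mid[1, "lat"], length(levels)), levels, tm)
  tc <- tailwind_component(w$u, w$v, az)
  data.frame(level = levels, altitude = pressure_to_altitude(levels),
             u = w$u, v = w$v, tailwind = tc$tailwind,
             crosswind = tc$crosswind)
}

#' Select the tailwind-maximising flight level
#'
#' Argmax of tailwind over the allowed pressure range; exact ties are
#' broken toward the highest pressure (lowest altitude).
#'
#' @param profile Data frame from [tailwind_profile()].
#' @param allowed_range Pressure range `c(min, max)` hPa (any order).
#' @return One-row data frame: `level`, `altitude`, `tailwind`.
#' @export
select_flight_level <- function(profile, allowed_range = c(1000, 500)) {
  r <- sort(allowed_range)
  p <- profile[profile$level >= r[1] & profile$level <= r[2], , drop = FALSE]
  if (nrow(p) == 0L) stop("no profile levels within the allowed range")
  p <- p[order(-p$level), , drop = FALSE]   # highest pressure first
  i <- which.max(p$tailwind)                # first max = tie toward low altitude
  data.frame(level = p$level[i], altitude = p$altitude[i],
             tailwind = p$tailwind[i])
}

# Internal: day-by-day segment kind lookup for a per-bird track.
day_kinds <- function(track, segments) {
  kind <- rep("travel", nrow(track))
  for (i in seq_len(nrow(segments))) {
    if (segments$kind[i] == "stopover") {
      sel <- track$date >= segments$start_date[i] &
        track$date <= segments$end_date[i]
      kind[sel] <- "stopover"
    }
  }
  kind
}

#' Annotate a track's travel steps with winds
#'
#' Builds one flight step per pair of consecutive travel days (stopover
#' days are excluded), samples the tailwind profile at each step midpoint
#' and selects the best allowed flight level.  Steps that fall outside the
#' wind field's hull are skipped with a warning.
#'
#' Equinox-flagged latitudes are linearly interpolated first (they are
#' needed for step geometry).
#'
#' @param track A per-bird track data frame.
#' @param segments Segment table from [segment_track()].
#' @param field A `wind_field`.
#' @param config A [wind_config()].
#' @return Data frame of flight steps: `bird_id`, `season`, `date`,
#'   `from_lat`, `from_lon`, `to_lat`, `to_lon`, `mid_lat`, `mid_lon`,
#'   `azimuth`, `level`, `altitude`, `tailwind`, `crosswind`,
#'   `tailwind_over_airspeed`.
#' @export
annotate_track <- function(track, segments, field, config = wind_config()) {
  track <- interpolate_equinox(track)
  kinds <- day_kinds(track, segments)
  n <- nrow(track)
  is_step <- kinds[-n] == "travel" & kinds[-1] == "travel" &
    as.numeric(track$date[-1] - track$date[-n]) == 1
  idx <- which(is_step)
  if (length(idx) == 0L) {
    return(data.frame(bird_id = character(), season = character(),
                      date = as.Date(character()), from_lat = numeric(),
                      from_lon = numeric(), to_lat = numeric(),
                      to_lon = numeric(), mid_lat = numeric(),
                      mid_lon = numeric(), azimuth = numeric(),
                      level = numeric(), altitude = numeric(),
                      tailwind = numeric(), crosswind = numeric(),
                      tailwind_over_airspeed = numeric()))
  }
  steps <- lapply(idx, function(i) {
    if (gc_distance_km(track$lat[i], track$lon[i],
                       track$lat[i + 1], track$lon[i + 1]) < 1e-6) {
      return(NULL)   # no displacement, no azimuth
    }
    prof <- tryCatch(
      tailwind_profile(field, track$lat[i], track$lon[i],
                       track$lat[i + 1], track$lon[i + 1], track$date[i],
                       config$levels),
      error = function(e) {
        warning("step on ", format(track$date[i]), " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(prof)) return(NULL)
    best <- select_flight_level(prof, config$allowed_range)
    mid <- gc_midpoint(track$lat[i], track$lon[i],
                       track$lat[i + 1], track$lon[i + 1])
    cw <- prof$crosswind[prof$level == best$level]
    data.frame(bird_id = track$bird_id[1],
               season = if ("season" %in% names(track)) track$season[1] else NA,
               date = track$date[i],
               from_lat = track$lat[i], from_lon = track$lon[i],
               to_lat = track$lat[i + 1], to_lon = track$lon[i + 1],
               mid_lat = mid[1, "lat"], mid_lon = mid[1, "lon"],
               azimuth = initial_bearing(track$lat[i], track$lon[i],
                                         track$lat[i + 1], track$lon[i + 1]),
               level = best$level, altitude = best$altitude,
               tailwind = best$tailwind, crosswind = cw,
               tailwind_over_airspeed = best$tailwind / config$airspeed)
  })
  out <- do.call(rbind, steps[!vapply(steps, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Mean tailwind per latitude bin
#'
#' Assigns flight steps to latitude bins by their midpoint latitude and
#' averages the selected-level tailwind per bin.
#'
#' @param steps Data frame from [annotate_track()] (one or many birds).
#' @param bin_edges Increasing vector of bin edges in degrees.
#' @return Data frame `bin_mid`, `mean_tailwind`, `mean_altitude`, `n`;
#'   empty bins are kept with `n = 0` and `NA` means.
#' @export
tailwind_by_latitude <- function(steps, bin_edges = seq(0, 70, by = 5)) {
  cuts <- cut(steps$mid_lat, breaks = bin_edges, right = FALSE)
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  agg <- function(x, f) {
    s <- tapply(x, cuts, f)
    as.numeric(s[levels(cuts)])
  }
  n <- as.integer(table(cuts)[levels(cuts)])
  data.frame(bin_mid = mids,
             mean_tailwind = ifelse(n > 0, agg(steps$tailwind, mean), NA_real_),
             mean_altitude = ifelse(n > 0, agg(steps$altitude, mean), NA_real_),
             n = n)
}
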