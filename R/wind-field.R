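# Gridded wind fields (u eastward, v northward, m/s) on a
# longitude x latitude x pressure-level x time grid, following the
# meteorological reanalysis component convention (the velocity air moves
# toward).  Synthetic fields are built from a closed form so that any node
# value is analytically known.

#' Construct a wind-field object
#'
#' Axes are normalised to strictly increasing order (arrays are reordered
#' accordingly), so downstream results are invariant to the storage order
#' of the input.
#'
#' @param lon,lat Axis values in decimal degrees.
#' @param level Pressure levels in hPa.
#' @param time POSIXct (UTC) axis.
#' @param u,v 4-d arrays `[lon, lat, level, time]`, m/s, finite everywhere.
#' @return A list of class `wind_field`.
#' @export
wind_field <- function(lon, lat, level, time, u, v) {
  time <- as.POSIXct(time, tz = "UTC")
  dims <- c(length(lon), length(lat), length(level), length(time))
  stopifnot(identical(dim(u), dims), identical(dim(v), dims))
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("u,v must be finite")
  ord <- list(order(lon), order(lat), order(level), order(time))
  u <- u[ord[[1]], ord[[2]], ord[[3]], ord[[4]], drop = FALSE]
  v <- v[ord[[1]], ord[[2]], ord[[3]], ord[[4]], drop = FALSE]
  lon <- lon[ord[[1]]]; lat <- lat[ord[[2]]]
  level <- level[ord[[3]]]; time <- time[ord[[4]]]
  for (ax in list(lon, lat, level, as.numeric(time))) {
    if (any(diff(ax) <= 0)) stop("axes must be strictly monotone")
  }
  structure(list(lon = lon, lat = lat, level = level, time = time,
                 u = u, v = v), class = "wind_field")
}

#' Closed-form synthetic wind at arbitrary points
#'
#' Evaluates the generator's analytic wind model: base + spatial gradients +
#' temporal ramp + pressure-Gaussian jet + latitude-travelling pulse (see
#' [wind_params()]).  This is the ground truth that gridded synthetic
#' fields are built from.
#'
#' @param params A [wind_params()].
#' @param lon,lat Degrees (vectorised).
#' @param level Pressure in hPa.
#' @param time POSIXct (UTC) or `Date`.
#' @param origin Temporal origin (`Date`); ramp and wave times are measured
#'   in days since `origin` at 00:00 UTC.
#' @return A data frame with `u` and `v` in m/s.
#' @export
wind_field_value <- function(params, lon, lat, level, time, origin) {
  t0 <- as.POSIXct(paste(format(as.Date(origin)), "00:00:00"), tz = "UTC")
  td <- as.numeric(as.POSIXct(time, tz = "UTC") - t0, units = "days")
  jet <- exp(-(level - params$jet_level)^2 / (2 * params$jet_width^2))
  wave <- exp(-(td - (lat - params$wave_lat0) / params$wave_rate)^2 /
                (2 * params$wave_sd^2))
  comp <- function(base, glat, glon, ramp, jamp, wamp) {
    base + glat * (lat - params$ref_lat) + glon * (lon - params$ref_lon) +
      ramp * td + jamp * jet + wamp * wave
  }
  data.frame(
    u = comp(params$base_u, params$grad_lat_u, params$grad_lon_u,
             params$ramp_u, params$jet_u, params$wave_u),
    v = comp(params$base_v, params$grad_lat_v, params$grad_lon_v,
             params$ramp_v, params$jet_v, params$wave_v))
}

#' Default grid specification covering a scenario
#'
#' @param scenario A [swift_scenario()].
#' @param lon_step,lat_step Grid spacing in degrees.
#' @param levels Pressure levels in hPa.
#' @param pad_deg Spatial margin beyond the waypoint bounding box.
#' @param pad_days Temporal margin beyond the scheduled dates (must cover
#'   departure jitter and counterfactual offsets).
#' @return A list `lon`, `lat`, `level`, `time` (daily at 12:00 UTC).
#' @export
default_wind_grid <- function(scenario, lon_step = 2.5, lat_step = 2,
                              levels = c(1000, 925, 850, 700, 600, 500),
                              pad_deg = 5, pad_days = NULL) {
  pts <- rbind(c(scenario$breeding_site[["lat"]], scenario$breeding_site[["lon"]]),
               c(scenario$wintering_site[["lat"]], scenario$wintering_site[["lon"]]),
               as.matrix(scenario$legs[, c("lat", "lon")]))
  if (is.null(pad_days)) pad_days <- ceiling(4 * scenario$departure_jitter_sd) + 8
  span <- sum(scenario$legs$travel_days + scenario$legs$stopover_days) +
    scenario$arrival_residency_days
  t0 <- as.POSIXct(paste(format(scenario$departure_date - pad_days), "12:00:00"),
                   tz = "UTC")
  t1 <- as.POSIXct(paste(format(scenario$departure_date + span + pad_days),
                         "12:00:00"), tz = "UTC")
  list(lon = seq(floor(min(pts[, 2]) - pad_deg), ceiling(max(pts[, 2]) + pad_deg),
                 by = lon_step),
       lat = seq(floor(min(pts[, 1]) - pad_deg), ceiling(max(pts[, 1]) + pad_deg),
                 by = lat_step),
       level = sort(levels, decreasing = TRUE),
       time = seq(t0, t1, by = 86400))
}

#' Simulate a gridded wind field for a scenario
#'
#' Fills a grid with the closed form of [wind_field_value()]; node values
#' are exactly retrievable analytically.
#'
#' @param scenario A [swift_scenario()] (supplies `wind` parameters and the
#'   temporal origin).
#' @param grid A grid spec, e.g. from [default_wind_grid()].
#' @param noise_sd Optional i.i.d. Gaussian node noise, m/s (default 0, the
#'   deterministic study field).
#' @param seed Seed for node noise (ignored when `noise_sd = 0`).
#' @return A `wind_field`.
#' @export
simulate_wind_field <- function(scenario, grid = default_wind_grid(scenario),
                                noise_sd = 0, seed = 1) {
  params <- scenario$wind
  if (!is.null(params$jet_level) &&
      (params$jet_u != 0 || params$jet_v != 0) &&
      !(params$jet_level %in% grid$level)) {
    stop("jet_level must be one of the grid levels")
  }
  pts <- rbind(as.matrix(scenario$legs[, c("lat", "lon")]),
               c(scenario$breeding_site[["lat"]], scenario$breeding_site[["lon"]]),
               c(scenario$wintering_site[["lat"]], scenario$wintering_site[["lon"]]))
  if (min(pts[, 1]) < min(grid$lat) || max(pts[, 1]) > max(grid$lat) ||
      min(pts[, 2]) < min(grid$lon) || max(pts[, 2]) > max(grid$lon)) {
    stop("grid does not cover the scenario's spatial extent")
  }
  g <- expand.grid(lon = grid$lon, lat = grid$lat, level = grid$level,
                   time = grid$time, KEEP.OUT.ATTRS = FALSE)
  w <- wind_field_value(params, g$lon, g$lat, g$level, g$time,
                        origin = scenario$departure_date)
  dims <- c(length(grid$lon), length(grid$lat), length(grid$level),
            length(grid$time))
  u <- array(w$u, dims)
  v <- array(w$v, dims)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 17L))
    u <- u + array(stats::rnorm(prod(dims), 0, noise_sd), dims)
    v <- v + array(stats::rnorm(prod(dims), 0, noise_sd), dims)
  }
  wind_field(grid$lon, grid$lat, grid$level, grid$time, u, v)
}

# Locate x on axis ax: bracketing lower index i and weight w in [0,1] for
# the upper node; exact hits get w = 0 on their own node.  Errors outside
# the hull (no extrapolation).
axis_locate <- function(x, ax, name, transform = identity) {
  if (any(x < ax[1] - 1e-9) || any(x > ax[length(ax)] + 1e-9)) {
    stop("query outside grid hull on axis ", name)
  }
  x <- pmin(pmax(x, ax[1]), ax[length(ax)])
  i <- findInterval(x, ax, rightmost.closed = TRUE, all.inside = TRUE)
  tx <- transform(x); ta <- transform(ax)
  w <- (tx - ta[i]) / (ta[i + 1] - ta[i])
  list(i = i, w = w)
}

#' Sample wind by interpolation
#'
#' Multilinear interpolation in longitude, latitude and time, linear in
#' log-pressure for the level axis, applied to u and v independently.  No
#' extrapolation: queries outside the grid hull are errors.
#'
#' @param field A `wind_field`.
#' @param lon,lat Query coordinates, degrees (vectorised).
#' @param level Query pressure, hPa.
#' @param time Query time, POSIXct (UTC).
#' @return Data frame with `u` and `v`, m/s.
#' @export
sample_wind <- function(field, lon, lat, level, time) {
  n <- max(length(lon), length(lat), length(level), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  level <- rep_len(level, n)
  tq <- rep_len(as.numeric(as.POSIXct(time, tz = "UTC")), n)
  ax <- list(
    axis_locate(lon, field$lon, "lon"),
    axis_locate(lat, field$lat, "lat"),
    axis_locate(level, field$level, "level", transform = log),
    axis_locate(tq, as.numeric(field$time), "time"))
  d <- c(length(field$lon), length(field$lat), length(field$level),
         length(field$time))
  interp_array <- function(arr) {
    # gather the 16 corner values, then reduce one axis at a time
    corners <- matrix(0, n, 16)
    cidx <- 0L
    for (dt in 0:1) for (dl in 0:1) for (dy in 0:1) for (dx in 0:1) {
      cidx <- cidx + 1L
      lin <- (ax[[1]]$i + dx) +
        d[1] * ((ax[[2]]$i + dy - 1) +
                  d[2] * ((ax[[3]]$i + dl - 1) +
                            d[3] * (ax[[4]]$i + dt - 1)))
      corners[, cidx] <- arr[lin]
    }
    # reduce lon (adjacent pairs), then lat, level, time
    red <- corners
    for (k in 1:4) {
      w <- ax[[k]]$w
      m <- ncol(red) / 2
      red <- red[, seq_len(m) * 2 - 1, drop = FALSE] * (1 - w) +
        red[, seq_len(m) * 2, drop = FALSE] * w
    }
    red[, 1]
  }
  data.frame(u = interp_array(field$u), v = interp_array(field$v))
}

#' Write / read a wind field as long-format CSV
#'
#' Plain-text serialization with columns
#' `time,level_hPa,lat,lon,u_ms,v_ms`; times are ISO 8601 UTC.
#'
#' @param field A `wind_field`.
#' @param path File path.
#' @return `read_wind_field` returns a `wind_field`.
#' @export
write_wind_field <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat, level = field$level,
                   time = format(field$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(time = g$time, level_hPa = g$level, lat = g$lat,
                    lon = g$lon, u_ms = as.vector(field$u),
                    v_ms = as.vector(field$v))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wind_field
#' @export
read_wind_field <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(x$lon)); lat <- sort(unique(x$lat))
  level <- sort(unique(x$level_hPa))
  time <- sort(unique(as.POSIXct(x$time, format = "%Y-%m-%dT%H:%M:%S",
                                 tz = "UTC")))
  dims <- c(length(lon), length(lat), length(level), length(time))
  ix <- cbind(match(x$lon, lon), match(x$lat, lat), match(x$level_hPa, level),
              match(as.POSIXct(x$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    time))
  u <- array(NA_real_, dims); v <- array(NA_real_, dims)
  u[ix] <- x$u_ms; v[ix] <- x$v_ms
  wind_field(lon, lat, level, time, u, v)
}

#' Write / read a wind field as CF-style NetCDF
#'
#' Dimensions `time, level, latitude, longitude`; variables `u`, `v` in
#' m/s.  Requires the optional `ncdf4` package.
#'
#' @param field A `wind_field`.
#' @param path File path.
#' @return `read_wind_field_nc` returns a `wind_field`.
#' @export
write_wind_field_nc <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the ncdf4 package is required for NetCDF output; ",
         "use write_wind_field() for CSV")
  }
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", field$lat)
  dlev <- ncdf4::ncdim_def("level", "hPa", field$level)
  dtim <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00",
                           as.numeric(field$time))
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dlon, dlat, dlev, dtim))
  vv <- ncdf4::ncvar_def("v", "m s-1", list(dlon, dlat, dlev, dtim))
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, field$u)
  ncdf4::ncvar_put(nc, vv, field$v)
  invisible(path)
}

#' @rdname write_wind_field_nc
#' @export
read_wind_field_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the ncdf4 package is required for NetCDF input")
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  wind_field(ncdf4::ncvar_get(nc, "longitude"),
             ncdf4::ncvar_get(nc, "latitude"),
             ncdf4::ncvar_get(nc, "level"),
             as.POSIXct(ncdf4::ncvar_get(nc, "time"),
                        origin = "1970-01-01", tz = "UTC"),
             ncdf4::ncvar_get(nc, "u"), ncdf4::ncvar_get(nc, "v"))
}
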