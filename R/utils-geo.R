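# Spherical-earth helpers shared across the pipeline.  All distances use a
# sphere of radius 6371.0 km so that route lengths and the detour definition
# are mutually consistent; the error relative to an ellipsoid is far below
# geolocator positional noise.

EARTH_RADIUS_KM <- 6371.0

#' Normalise longitudes to (-180, 180]
#'
#' @param lon Longitudes in decimal degrees (vectorised).
#' @return Longitudes wrapped into (-180, 180].
#' @export
wrap_lon <- function(lon) {
  x <- ((lon + 180) %% 360) - 180
  x[x == -180] <- 180
  x
}

#' Circular mean of longitudes
#'
#' Averages longitudes on the circle so that, e.g., fixes at 179.5 E and
#' 179.5 W average to 180, not 0.
#'
#' @param lon Longitudes in decimal degrees.
#' @param na.rm Drop missing values first.
#' @return A single longitude in (-180, 180], or `NA` if no values remain.
#' @export
circular_mean_lon <- function(lon, na.rm = TRUE) {
  if (na.rm) lon <- lon[!is.na(lon)]
  if (length(lon) == 0L) return(NA_real_)
  r <- lon * pi / 180
  wrap_lon(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance in kilometres.
#' @export
#' @examples
#' gc_distance_km(0, 0, 0, 90)  # quarter circumference, ~10007.5 km
gc_distance_km <- function(lat1, lon1, lat2, lon2) {
  if (anyNA(c(lat1, lat2))) stop("undefined latitude in distance computation")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing
#'
#' Forward azimuth at the first point of the great circle towards the second,
#' clockwise from true north.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Azimuth in degrees, in [0, 360).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  same <- abs(lat1 - lat2) < 1e-12 & abs(wrap_lon(lon1 - lon2)) < 1e-12
  if (any(same)) stop("bearing undefined for identical points")
  antip <- abs(lat1 + lat2) < 1e-9 & abs(abs(wrap_lon(lon1 - lon2)) - 180) < 1e-9
  if (any(antip)) stop("bearing undefined for antipodal points")
  # spherical forward azimuth, consistent with the spherical-earth distances
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- wrap_lon(lon2 - lon1) * pi / 180
  b <- atan2(sin(dl) * cos(p2),
             cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)) * 180 / pi
  b %% 360
}

#' Spherical centroid of a point cloud
#'
#' Mean of the unit vectors on the sphere, projected back to lat/lon.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @return Named numeric vector `c(lat = , lon = )`.
#' @export
spherical_centroid <- function(lat, lon) {
  la <- lat * pi / 180
  lo <- lon * pi / 180
  x <- mean(cos(la) * cos(lo))
  y <- mean(cos(la) * sin(lo))
  z <- mean(sin(la))
  c(lat = atan2(z, sqrt(x^2 + y^2)) * 180 / pi,
    lon = wrap_lon(atan2(y, x) * 180 / pi))
}

# Points at fractions f (vector in [0,1]) along the great circle between two
# sites, by spherical linear interpolation (constant angular speed).
gc_fraction_points <- function(lat1, lon1, lat2, lon2, f) {
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(lat1, lon1)
  b <- to_xyz(lat2, lon2)
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) {
    return(cbind(lat = rep(lat1, length(f)), lon = rep(lon1, length(f))))
  }
  w1 <- sin((1 - f) * omega) / sin(omega)
  w2 <- sin(f * omega) / sin(omega)
  x <- w1 * a[1] + w2 * b[1]
  y <- w1 * a[2] + w2 * b[2]
  z <- w1 * a[3] + w2 * b[3]
  cbind(lat = atan2(z, sqrt(x^2 + y^2)) * 180 / pi,
        lon = wrap_lon(atan2(y, x) * 180 / pi))
}

# Spherical midpoint of two points.
gc_midpoint <- function(lat1, lon1, lat2, lon2) {
  p <- geosphere::midPoint(cbind(lon1, lat1), cbind(lon2, lat2))
  cbind(lat = p[, 2], lon = wrap_lon(p[, 1]))
}

# Derive a per-stream 32-bit seed from a master seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483647)
}
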