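# Scripted migration scenarios.  A scenario fixes the study conditions for
# the synthetic cohort: sites, leg schedule, season, departure date and
# its between-bird spread, geolocator noise, equinox masking and the
# structured wind field.  Identical (scenario, seed) pairs reproduce
# byte-identical data.

#' Wind-field structure parameters
#'
#' Closed-form components of the synthetic wind field.  Every term is
#' defined per wind component (u eastward, v northward, m/s):
#' a constant base, linear spatial gradients, a linear temporal ramp, a
#' Gaussian jet in pressure centred on `jet_level`, and an optional
#' latitude-travelling Gaussian pulse (a wind "wave" that moves poleward at
#' `wave_rate` degrees/day, emulating a synoptic system tracking the
#' migration schedule).  The temporal origin of ramp and wave is the
#' scenario departure date.
#'
#' @param base_u,base_v Base wind, m/s.
#' @param grad_lat_u,grad_lat_v Gradient in latitude, m/s per degree.
#' @param grad_lon_u,grad_lon_v Gradient in longitude, m/s per degree.
#' @param ramp_u,ramp_v Temporal ramp, m/s per day since departure.
#' @param jet_u,jet_v Jet amplitude, m/s.
#' @param jet_level Jet centre, hPa; must be one of the grid levels.
#' @param jet_width Jet Gaussian width, hPa.
#' @param wave_u,wave_v Travelling-pulse amplitude, m/s.
#' @param wave_lat0 Latitude of the pulse at the departure date, degrees.
#' @param wave_rate Pulse propagation rate, degrees latitude per day.
#' @param wave_sd Pulse width, days.
#' @param ref_lat,ref_lon Reference point for the spatial gradients.
#' @return A list of class `wind_params`.
#' @export
wind_params <- function(base_u = 0, base_v = 0,
                        grad_lat_u = 0, grad_lat_v = 0,
                        grad_lon_u = 0, grad_lon_v = 0,
                        ramp_u = 0, ramp_v = 0,
                        jet_u = 0, jet_v = 0, jet_level = 700, jet_width = 80,
                        wave_u = 0, wave_v = 0, wave_lat0 = 0,
                        wave_rate = 4, wave_sd = 2,
                        ref_lat = 35, ref_lon = 10) {
  structure(as.list(environment()), class = "wind_params")
}

#' Define a scripted migration scenario
#'
#' @param breeding_site,wintering_site Named numeric vectors `c(lat=, lon=)`.
#' @param legs Data frame with one row per leg: `lat`, `lon` (waypoint),
#'   `travel_days` (>= 1 daily displacements at constant per-leg great-circle
#'   speed) and `stopover_days` (>= 0 stationary days at the waypoint).  The
#'   last waypoint must be the destination site.
#' @param season `"autumn"` or `"spring"`.
#' @param departure_date Scheduled departure (`Date` or string).
#' @param n_birds Number of birds in the cohort.
#' @param noise_sd_lat,noise_sd_lon Geolocator noise SD in degrees.  The
#'   defaults (1.0 and 0.5) are conventional magnitudes for GLS daily
#'   positions and are deliberately config-exposed, not hard-coded.
#' @param equinox_window Half-width (days) of the latitude-masking window
#'   around Mar 20 / Sep 22 applied to observed tracks; 0 disables masking.
#' @param departure_jitter_sd Between-bird SD of departure date, days
#'   (rounded normal deviates).
#' @param arrival_residency_days Stationary days appended at the destination
#'   so that arrival can be detected as the start of a terminal residency.
#' @param wind Per-scenario [wind_params()].
#' @return A list of class `swift_scenario`.
#' @export
swift_scenario <- function(breeding_site, wintering_site, legs, season,
                           departure_date, n_birds = 19,
                           noise_sd_lat = 1.0, noise_sd_lon = 0.5,
                           equinox_window = 10, departure_jitter_sd = 0,
                           arrival_residency_days = 10,
                           wind = wind_params()) {
  season <- match.arg(season, c("autumn", "spring"))
  stopifnot(is.data.frame(legs),
            all(c("lat", "lon", "travel_days", "stopover_days") %in% names(legs)))
  if (nrow(legs) == 0L || sum(legs$travel_days + legs$stopover_days) == 0) {
    stop("zero-length schedule")
  }
  if (any(legs$travel_days < 0) || any(legs$stopover_days < 0)) {
    stop("travel and stopover days must be >= 0")
  }
  if (noise_sd_lat < 0 || noise_sd_lon < 0) stop("noise SDs must be >= 0")
  from <- if (season == "autumn") breeding_site else wintering_site
  to <- if (season == "autumn") wintering_site else breeding_site
  pts <- rbind(c(from["lat"], from["lon"]),
               as.matrix(legs[, c("lat", "lon")]))
  seg_d <- gc_distance_km(pts[-nrow(pts), 1], pts[-nrow(pts), 2],
                          pts[-1, 1], pts[-1, 2])
  if (any(seg_d < 1e-6 & legs$travel_days > 0)) {
    stop("identical consecutive sites with nonzero travel days")
  }
  if (gc_distance_km(legs$lat[nrow(legs)], legs$lon[nrow(legs)],
                     to["lat"], to["lon"]) > 1) {
    stop("legs must end at the destination site")
  }
  structure(list(
    breeding_site = breeding_site, wintering_site = wintering_site,
    legs = legs, season = season,
    departure_date = as.Date(departure_date), n_birds = as.integer(n_birds),
    noise_sd_lat = noise_sd_lat, noise_sd_lon = noise_sd_lon,
    equinox_window = equinox_window,
    departure_jitter_sd = departure_jitter_sd,
    arrival_residency_days = as.integer(arrival_residency_days),
    wind = wind), class = "swift_scenario")
}

# Shared sites for the default scenarios: a Swedish Lapland breeding colony
# and a sub-Saharan wintering region.
lapland_site <- function() c(lat = 67.8, lon = 20.3)
subsahara_site <- function() c(lat = 5.5, lon = 17.5)

#' Default autumn scenario
#'
#' Nineteen birds leave Swedish Lapland in mid August, move southeast across
#' the Baltic (with a short initial stopover north of 55 N), then south and
#' southwest to Iberia, cross the Sahara with a Sahel stage, and reach the
#' sub-Saharan wintering area ~42 days after departure.  Wind defaults give
#' modest low-altitude tailwind support (a southward jet near 850 hPa).
#'
#' @param n_birds Cohort size.
#' @param departure_jitter_sd Between-bird departure SD in days.
#' @param initial_stopover_prob Probability that a bird performs the short
#'   initial stopover north of 55 N (about a third of tracked birds did).
#' @param ... Further arguments passed to [swift_scenario()].
#' @return A `swift_scenario`.
#' @export
autumn_scenario <- function(n_birds = 19, departure_jitter_sd = 10,
                            initial_stopover_prob = 6 / 19, ...) {
  legs <- data.frame(
    lat = c(59.0, 47.0, 40.5, 16.0, 5.5),
    lon = c(27.0, 9.0, -4.5, 0.5, 17.5),
    travel_days = c(2, 3, 2, 5, 4),
    stopover_days = c(1, 3, 14, 6, 0))
  sc <- swift_scenario(lapland_site(), subsahara_site(), legs,
                       season = "autumn", departure_date = "2019-08-15",
                       n_birds = n_birds,
                       departure_jitter_sd = departure_jitter_sd,
                       wind = wind_params(base_u = 1, base_v = -0.5,
                                          jet_v = -2.5, jet_level = 850,
                                          jet_width = 80),
                       ...)
  sc$initial_stopover_prob <- initial_stopover_prob
  sc$optional_initial_stop <- TRUE
  sc
}

#' Default spring scenario
#'
#' Twenty birds leave the wintering area in mid May, cross West Africa and
#' the Sahara to a single Mediterranean stopover, then fly to Lapland,
#' arriving ~15 days after departure.  Wind defaults give strong northward
#' tailwind support near 700 hPa plus a poleward-travelling pulse that
#' tracks the scheduled passage, so that the actual departure date is the
#' most favourable in the +/- 3 day window.
#'
#' @inheritParams autumn_scenario
#' @return A `swift_scenario`.
#' @export
spring_scenario <- function(n_birds = 20, departure_jitter_sd = 6, ...) {
  legs <- data.frame(
    lat = c(35.5, 67.8),
    lon = c(-2.5, 20.3),
    travel_days = c(5, 6),
    stopover_days = c(4, 0))
  sc <- swift_scenario(lapland_site(), subsahara_site(), legs,
                       season = "spring", departure_date = "2020-05-14",
                       n_birds = n_birds,
                       departure_jitter_sd = departure_jitter_sd,
                       wind = wind_params(base_u = 0.5, base_v = 2,
                                          jet_v = 6, jet_level = 700,
                                          jet_width = 90,
                                          wave_v = 3, wave_lat0 = 5.5,
                                          wave_rate = 62.3 / 15, wave_sd = 2.5),
                       ...)
  sc$initial_stopover_prob <- 0
  sc
}

#' Single-leg planted-advantage scenario
#'
#' A stripped-down northbound spring schedule with no stopover, one bird per
#' simulation, and a wind field whose only structure is a
#' latitude-travelling tailwind pulse locked to the scheduled passage.  By
#' construction the actual departure date maximises en-route tailwind, so
#' shifted departures lose wind support at every latitude - the
#' ground-truth case for the departure counterfactual.
#'
#' @param wave_v Pulse amplitude, m/s.
#' @param wave_sd Pulse width, days.
#' @param ... Further arguments passed to [swift_scenario()].
#' @return A `swift_scenario`.
#' @export
planted_advantage_scenario <- function(wave_v = 5, wave_sd = 2, ...) {
  rate <- 60 / 12   # degrees latitude per day, matching the single leg
  legs <- data.frame(lat = 65.5, lon = 17.5, travel_days = 12,
                     stopover_days = 0)
  sc <- swift_scenario(c(lat = 65.5, lon = 17.5), c(lat = 5.5, lon = 17.5),
                       legs, season = "spring",
                       departure_date = "2020-05-05", n_birds = 1,
                       equinox_window = 0, departure_jitter_sd = 0,
                       wind = wind_params(wave_v = wave_v, wave_lat0 = 5.5,
                                          wave_rate = rate, wave_sd = wave_sd),
                       ...)
  sc$initial_stopover_prob <- 0
  sc
}
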