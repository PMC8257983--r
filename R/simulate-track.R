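# Scripted track simulation.  True positions follow the great-circle leg
# schedule at constant per-leg daily displacement and hold station during
# stopovers; observations add independent Gaussian noise per day (no
# autocorrelation) and mask latitudes in the equinox window, emulating
# 1-day GLS average locations.

# Build one bird's true daily positions from the scenario schedule.
# Returns a data.frame date/lat/lon plus the departure and arrival dates.
script_true_track <- function(scenario, departure_date, with_initial_stop = TRUE) {
  from <- if (scenario$season == "autumn") scenario$breeding_site else scenario$wintering_site
  legs <- scenario$legs
  if (!with_initial_stop && nrow(legs) > 1) {
    # the optional short initial stopover is the first leg's stationary days
    legs$stopover_days[1] <- 0
  }
  lat <- from[["lat"]]; lon <- from[["lon"]]
  cur <- c(lat, lon)
  for (i in seq_len(nrow(legs))) {
    Tt <- legs$travel_days[i]
    if (Tt > 0) {
      pts <- gc_fraction_points(cur[1], cur[2], legs$lat[i], legs$lon[i],
                                seq_len(Tt) / Tt)
      lat <- c(lat, pts[, "lat"]); lon <- c(lon, pts[, "lon"])
    }
    Ss <- legs$stopover_days[i]
    if (Ss > 0) {
      lat <- c(lat, rep(legs$lat[i], Ss)); lon <- c(lon, rep(legs$lon[i], Ss))
    }
    cur <- c(legs$lat[i], legs$lon[i])
  }
  arrival_offset <- length(lat) - 1L
  Rr <- scenario$arrival_residency_days
  if (Rr > 0) {
    lat <- c(lat, rep(cur[1], Rr)); lon <- c(lon, rep(cur[2], Rr))
  }
  data.frame(date = departure_date + seq_along(lat) - 1L,
             lat = unname(lat), lon = unname(lon),
             arrival = departure_date + arrival_offset)
}

# Ground-truth residency runs: maximal runs of >= 2 consecutive identical
# positions.  The day the bird arrives at a site is part of the run (daily
# positions cannot separate the arrival flight from residency on that day).
true_stopovers <- function(true_track) {
  n <- nrow(true_track)
  same <- c(FALSE, abs(diff(true_track$lat)) < 1e-9 &
              abs(diff(true_track$lon)) < 1e-9)
  run_id <- cumsum(!same)
  runs <- split(seq_len(n), run_id)
  runs <- runs[vapply(runs, length, integer(1)) >= 2L]
  if (length(runs) == 0L) {
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()), lat = numeric(),
                      lon = numeric(), duration = integer(),
                      terminal = logical()))
  }
  out <- do.call(rbind, lapply(runs, function(ix) {
    data.frame(start_date = true_track$date[ix[1]],
               end_date = true_track$date[ix[length(ix)]],
               lat = true_track$lat[ix[1]], lon = true_track$lon[ix[1]],
               duration = length(ix),
               terminal = ix[length(ix)] == n)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of scripted geolocator tracks
#'
#' @param scenario A [swift_scenario()].
#' @param seed Integer master seed; per-bird streams are derived
#'   deterministically from it by bird index.
#' @return A list with
#'   \describe{
#'     \item{true}{exact daily positions (`bird_id`, `season`, `date`,
#'       `lat`, `lon`, `lat_valid = TRUE`);}
#'     \item{observed}{noisy positions with equinox latitudes masked
#'       (`lat = NA`, `lat_valid = FALSE`);}
#'     \item{script}{per-bird truth: departure/arrival dates, stopover count
#'       and the residency-run table (`stopovers`).}
#'   }
#' @export
#' @examples
#' sim <- simulate_tracks(spring_scenario(n_birds = 2), seed = 1)
#' head(sim$observed)
simulate_tracks <- function(scenario, seed) {
  stopifnot(inherits(scenario, "swift_scenario"))
  n <- scenario$n_birds
  set.seed(derive_seed(seed, 0L))
  jitter <- if (scenario$departure_jitter_sd > 0) {
    round(stats::rnorm(n, 0, scenario$departure_jitter_sd))
  } else rep(0, n)
  # only scenarios that mark the first-leg stop as optional (the short
  # autumn stop north of the breeding latitude cutoff) draw its presence
  has_init <- if (isTRUE(scenario$optional_initial_stop)) {
    stats::runif(n) < scenario$initial_stopover_prob
  } else rep(TRUE, n)
  true_list <- vector("list", n)
  obs_list <- vector("list", n)
  script_list <- vector("list", n)
  stops_list <- vector("list", n)
  for (b in seq_len(n)) {
    id <- sprintf("%s_%02d", substr(scenario$season, 1, 3), b)
    dep <- scenario$departure_date + jitter[b]
    tt <- script_true_track(scenario, dep, with_initial_stop = has_init[b])
    arrival <- tt$arrival[1]
    tt$arrival <- NULL
    set.seed(derive_seed(seed, b))
    obs <- tt
    obs$lat <- obs$lat + stats::rnorm(nrow(tt), 0, scenario$noise_sd_lat)
    obs$lon <- wrap_lon(obs$lon + stats::rnorm(nrow(tt), 0, scenario$noise_sd_lon))
    obs$lat_valid <- TRUE
    if (scenario$equinox_window > 0) {
      obs <- flag_equinox(obs, scenario$equinox_window)
    }
    st <- true_stopovers(tt)
    st <- cbind(bird_id = id, st)
    true_list[[b]] <- cbind(bird_id = id, season = scenario$season, tt,
                            lat_valid = TRUE)
    obs_list[[b]] <- cbind(bird_id = id, season = scenario$season, obs)
    script_list[[b]] <- data.frame(
      bird_id = id, season = scenario$season,
      departure_date = dep, arrival_date = arrival,
      total_days = as.integer(arrival - dep),
      n_stopovers = sum(!st$terminal),
      stopover_dates = sum(st$duration[!st$terminal]))
    stops_list[[b]] <- st
  }
  script <- do.call(rbind, script_list)
  rownames(script) <- NULL
  stops <- do.call(rbind, stops_list)
  rownames(stops) <- NULL
  list(true = do.call(rbind, true_list),
       observed = do.call(rbind, obs_list),
       script = script,
       stopovers = stops)
}

#' Write / read daily-position tracks as CSV
#'
#' Columns `bird_id,season,date,lat,lon,lat_valid` with ISO dates; the
#' pipeline's on-disk spine.
#'
#' @param track Track data frame (one or many birds).
#' @param path File path.
#' @return `read_tracks` returns the data frame with `Date` dates.
#' @export
write_tracks <- function(track, path) {
  out <- track
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x$lat_valid <- as.logical(x$lat_valid)
  x
}

#' Split a multi-bird track table into per-bird tracks
#'
#' @param track Track data frame with a `bird_id` column.
#' @return Named list of per-bird data frames, date-ordered.
#' @export
split_birds <- function(track) {
  lapply(split(track, track$bird_id), function(d) d[order(d$date), , drop = FALSE])
}
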