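# Stopover segmentation: partition a daily track into periods of restricted
# geographic movement ("stopovers") and travel days.  A stopover is a
# maximal run of at least `min_days` consecutive days whose positions all
# lie within `radius_km` of the run's iteratively updated spherical
# centroid (greedy forward pass), followed by a merge pass that rejoins
# runs split by a single noisy fix.

#' Segmentation configuration
#'
#' @param radius_km Residency radius in km (> 0).  The default 200 km
#'   matches the positional scatter of GLS daily fixes.
#' @param min_days Minimum stopover duration in days (>= 1; default 2, the
#'   shortest stopovers reported for tracked swifts).
#' @param initial_lat_cutoff Latitude (degrees) above which an autumn
#'   stopover counts as "initial" (soon after leaving the breeding area).
#' @param max_merge_gap Maximum number of intervening days across which two
#'   co-located stopover runs are merged (see Details of
#'   [segment_track()]).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(radius_km = 200, min_days = 2,
                                initial_lat_cutoff = 55, max_merge_gap = 1) {
  if (radius_km <= 0) stop("radius_km must be > 0")
  if (min_days < 1) stop("min_days must be >= 1")
  structure(list(radius_km = radius_km, min_days = min_days,
                 initial_lat_cutoff = initial_lat_cutoff,
                 max_merge_gap = max_merge_gap),
            class = "segmentation_config")
}

#' Segment a track into stopovers and travel
#'
#' Greedy forward pass: a day joins the current run only if it lies within
#' `radius_km` of the run's current spherical centroid (recomputed as days
#' accrete); otherwise the run closes and a new one starts.  Runs of at
#' least `min_days` days become stopovers; all other days are travel.  A
#' single noisy fix can split one true residency into two adjacent runs, so
#' a merge pass rejoins consecutive stopovers whose centroids are within
#' `radius_km` of each other and that are separated by at most
#' `max_merge_gap` days (the gap days are reassigned to the stopover).
#'
#' Equinox-flagged latitudes are linearly interpolated first (the run
#' definition needs contiguous positions).
#'
#' An autumn stopover is flagged `is_initial` when its centroid latitude
#' exceeds `initial_lat_cutoff`; a spring stopover when it begins on the
#' track's first day (i.e. at the departure site).
#'
#' @param track A per-bird track data frame (`date`, `lat`, `lon`,
#'   `lat_valid`, optionally `season`).
#' @param config A [segmentation_config()].
#' @return Data frame of segments tiling the track: `kind`
#'   (`stopover`/`travel`), `start_date`, `end_date`, `centroid_lat`,
#'   `centroid_lon`, `duration` (days, inclusive), `is_initial`.
#' @export
segment_track <- function(track, config = segmentation_config()) {
  if (nrow(track) < 2L) stop("track must span at least 2 days")
  track <- track[order(track$date), , drop = FALSE]
  if (any(diff(as.numeric(track$date)) != 1)) stop("track dates must be contiguous")
  track <- interpolate_equinox(track)
  n <- nrow(track)

  run_id <- integer(n)
  run_id[1] <- 1L
  run_lat <- track$lat[1]; run_lon <- track$lon[1]
  cen <- c(lat = run_lat, lon = run_lon)
  for (j in 2:n) {
    if (gc_distance_km(track$lat[j], track$lon[j], cen["lat"], cen["lon"]) <=
        config$radius_km) {
      run_id[j] <- run_id[j - 1]
      run_lat <- c(run_lat, track$lat[j]); run_lon <- c(run_lon, track$lon[j])
    } else {
      run_id[j] <- run_id[j - 1] + 1L
      run_lat <- track$lat[j]; run_lon <- track$lon[j]
    }
    cen <- spherical_centroid(run_lat, run_lon)
  }
  runs <- split(seq_len(n), run_id)
  is_stop <- vapply(runs, length, integer(1)) >= config$min_days

  stop_runs <- runs[is_stop]
  # merge pass
  repeat {
    if (length(stop_runs) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(stop_runs) - 1L)) {
      a <- stop_runs[[k]]; b <- stop_runs[[k + 1]]
      gap <- b[1] - a[length(a)] - 1L
      ca <- spherical_centroid(track$lat[a], track$lon[a])
      cb <- spherical_centroid(track$lat[b], track$lon[b])
      if (gap <= config$max_merge_gap &&
          gc_distance_km(ca["lat"], ca["lon"], cb["lat"], cb["lon"]) <=
          config$radius_km) {
        stop_runs[[k]] <- a[1]:b[length(b)]
        stop_runs[[k + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  in_stop <- rep(FALSE, n)
  for (r in stop_runs) in_stop[r] <- TRUE
  seg_id <- cumsum(c(TRUE, in_stop[-1] != in_stop[-n]))
  season <- if ("season" %in% names(track)) track$season[1] else NA_character_
  segs <- do.call(rbind, lapply(split(seq_len(n), seg_id), function(ix) {
    cen <- spherical_centroid(track$lat[ix], track$lon[ix])
    data.frame(kind = if (in_stop[ix[1]]) "stopover" else "travel",
               start_date = track$date[ix[1]],
               end_date = track$date[ix[length(ix)]],
               centroid_lat = unname(cen["lat"]),
               centroid_lon = unname(cen["lon"]),
               duration = length(ix))
  }))
  rownames(segs) <- NULL
  segs$is_initial <- segs$kind == "stopover" & (
    if (identical(season, "spring")) segs$start_date == track$date[1]
    else segs$centroid_lat > config$initial_lat_cutoff)
  if ("bird_id" %in% names(track)) {
    segs <- cbind(bird_id = track$bird_id[1], segs)
  }
  segs
}

#' Travel / stopover day totals from a segment table
#'
#' @param segments Segment table from [segment_track()] for one bird; must
#'   tile the track without overlap.
#' @return A list: `travel_days`, `stopover_days` (their sum is the track's
#'   total day count) and `n_stops`, the number of non-initial stopovers.
#' @export
count_travel_days <- function(segments) {
  segments <- segments[order(segments$start_date), , drop = FALSE]
  if (nrow(segments) > 1L) {
    gaps <- as.numeric(segments$start_date[-1] - segments$end_date[-nrow(segments)])
    if (any(gaps != 1)) stop("segments must tile the track without overlap")
  }
  list(travel_days = sum(segments$duration[segments$kind == "travel"]),
       stopover_days = sum(segments$duration[segments$kind == "stopover"]),
       n_stops = sum(segments$kind == "stopover" & !segments$is_initial))
}

#' Stopover recovery error against a scripted truth
#'
#' Compares recovered stopover segments with the ground-truth residency
#' runs of a simulated bird.  Terminal residencies (the destination) are
#' excluded on both sides.  Recovered stopovers are matched to true ones by
#' maximal date overlap; an unmatched true stopover contributes its full
#' duration to the duration error.
#'
#' @param truth Data frame of true residency runs for one bird
#'   (`start_date`, `end_date`, `duration`, `terminal`), as in the
#'   `stopovers` element of [simulate_tracks()].
#' @param segments Recovered segment table for the same bird.
#' @return A list: `count_error` (absolute difference in stopover count)
#'   and `duration_errors` (absolute day errors, one per true stopover).
#' @export
stopover_recovery_error <- function(truth, segments) {
  truth <- truth[!truth$terminal, , drop = FALSE]
  last_day <- max(segments$end_date)
  rec <- segments[segments$kind == "stopover" & segments$end_date < last_day, ,
                  drop = FALSE]
  dur_err <- vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(rec) == 0L) return(truth$duration[i])
    ov <- pmax(0, as.numeric(pmin(rec$end_date, truth$end_date[i]) -
                               pmax(rec$start_date, truth$start_date[i])) + 1)
    if (max(ov) == 0) return(truth$duration[i])
    abs(rec$duration[which.max(ov)] - truth$duration[i])
  }, numeric(1))
  list(count_error = abs(nrow(rec) - nrow(truth)),
       duration_errors = dur_err)
}

#' Write a segment table as CSV
#'
#' @param segments Segment table (one or many birds).
#' @param path File path.
#' @export
write_segments <- function(segments, path) {
  out <- segments
  out$start_date <- format(out$start_date)
  out$end_date <- format(out$end_date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
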