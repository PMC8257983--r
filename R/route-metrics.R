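# Per-bird, per-season migration characteristics: route length, detour
# relative to the great circle, migration and travel speeds, percent of
# migration spent in flight, barrier-crossing durations, and paired
# seasonal comparisons.

#' Route length of a track
#'
#' Sum of consecutive-day great-circle distances.  Equinox-flagged
#' latitudes are linearly interpolated first; interpolated legs contribute
#' to the sum.
#'
#' @param track A per-bird track data frame (`date`, `lat`, `lon`,
#'   `lat_valid`).
#' @return Distance in km (0 for a single-point track).
#' @export
route_length <- function(track) {
  if (nrow(track) < 2L) return(0)
  track <- interpolate_equinox(track[order(track$date), , drop = FALSE])
  n <- nrow(track)
  sum(gc_distance_km(track$lat[-n], track$lon[-n],
                     track$lat[-1], track$lon[-1]))
}

#' Detour relative to the great-circle distance
#'
#' `100 * (route_length / gc_distance(first, last) - 1)`, in percent.
#'
#' @param track A per-bird track data frame; first and last positions must
#'   have valid latitude.
#' @return Detour in percent (>= 0 up to interpolation tolerance).
#' @export
detour_percent <- function(track) {
  track <- track[order(track$date), , drop = FALSE]
  n <- nrow(track)
  if (is.na(track$lat[1]) || is.na(track$lat[n])) {
    stop("track endpoints must have valid latitude")
  }
  d <- gc_distance_km(track$lat[1], track$lon[1], track$lat[n], track$lon[n])
  if (d < 1e-9) stop("track endpoints are identical; detour undefined")
  100 * (route_length(track) / d - 1)
}

#' Per-bird migration summary
#'
#' Departure is the first day of the first travel segment (the day the bird
#' leaves the origin residency); arrival is the first day of the terminal
#' residency (or the last track day if the track ends in travel).  Days are
#' counted over the dates after departure up to and including arrival, so
#' `total_days = arrival_date - departure_date` (a difference of dates, the
#' convention that makes 15 Aug to 26 Sep equal 42 days) and
#' `travel_days + stopover_days = total_days`.
#'
#' `travel_speed = total_distance / travel_days`;
#' `migration_speed = total_distance / (total_days - initial_stopover_days)`
#' (initial stopovers, flagged by segmentation, are excluded from the
#' denominator); `percent_flight = 100 * travel_days / total_days`.
#'
#' @param track A per-bird track data frame.
#' @param segments Segment table from [segment_track()] tiling the track.
#' @return One-row data frame with the Table-style migration
#'   characteristics.
#' @export
migration_summary <- function(track, segments) {
  track <- interpolate_equinox(track[order(track$date), , drop = FALSE])
  segments <- segments[order(segments$start_date), , drop = FALSE]
  trav <- segments[segments$kind == "travel", , drop = FALSE]
  if (nrow(trav) == 0L) stop("no travel days in track")
  departure <- trav$start_date[1]
  # arrival = first day of the terminal residency; a stopover reaching to
  # within 2 days of the track end counts as terminal, so that a single
  # noisy fix on the last day cannot push the arrival to the track end
  stops <- segments[segments$kind == "stopover", , drop = FALSE]
  track_end <- segments$end_date[nrow(segments)]
  arrival <- if (nrow(stops) > 0 &&
                 as.numeric(track_end - stops$end_date[nrow(stops)]) <= 2) {
    stops$start_date[nrow(stops)]
  } else {
    track_end
  }
  total_days <- as.integer(arrival - departure)
  span <- track$date > departure & track$date <= arrival
  kinds <- day_kinds(track, segments)
  # the arrival day itself is the flight into the destination residency and
  # counts as travel, even though its position already sits at the site
  stopover_days <- sum(span & kinds == "stopover" & track$date < arrival)
  travel_days <- total_days - stopover_days
  init <- segments[segments$kind == "stopover" & segments$is_initial, ,
                   drop = FALSE]
  initial_days <- 0L
  for (i in seq_len(nrow(init))) {
    initial_days <- initial_days +
      sum(span & track$date >= init$start_date[i] & track$date <= init$end_date[i])
  }
  sub <- track[track$date >= departure & track$date <= arrival, , drop = FALSE]
  dist <- route_length(sub)
  n_stops <- sum(segments$kind == "stopover" & !segments$is_initial &
                   segments$start_date > departure & segments$start_date < arrival)
  data.frame(
    bird_id = if ("bird_id" %in% names(track)) track$bird_id[1] else NA,
    season = if ("season" %in% names(track)) track$season[1] else NA,
    departure_date = departure, arrival_date = arrival,
    travel_days = travel_days, stopover_days = stopover_days,
    total_days = total_days, total_distance = dist,
    detour = detour_percent(sub),
    travel_speed = dist / travel_days,
    migration_speed = dist / (total_days - initial_days),
    percent_flight = 100 * travel_days / total_days,
    n_stops = n_stops)
}

#' Barrier-crossing durations
#'
#' Days between the first entry into the latitude band
#' `[lat_south, lat_north]` and the first exit on its far side, in the
#' track's direction of travel; `travel_days` excludes stopover days spent
#' inside the band.
#'
#' @param track A per-bird track data frame (crossing the band).
#' @param segments Segment table for the same bird.
#' @param lat_north,lat_south Band edges in degrees (`lat_north` >
#'   `lat_south`).
#' @return A list: `total_days`, `travel_days`.
#' @export
barrier_crossing <- function(track, segments, lat_north = 40, lat_south = 20) {
  stopifnot(lat_north > lat_south)
  track <- interpolate_equinox(track[order(track$date), , drop = FALSE])
  n <- nrow(track)
  southbound <- track$lat[n] < track$lat[1]
  if (southbound) {
    entry <- which(track$lat <= lat_north)[1]
    if (is.na(entry)) stop("track never enters the latitude band")
    exit <- which(track$lat < lat_south & seq_len(n) > entry)[1]
    if (is.na(exit)) stop("track never exits the latitude band")
  } else {
    entry <- which(track$lat >= lat_south)[1]
    if (is.na(entry)) stop("track never enters the latitude band")
    exit <- which(track$lat > lat_north & seq_len(n) > entry)[1]
    if (is.na(exit)) stop("track never exits the latitude band")
  }
  total <- as.integer(track$date[exit] - track$date[entry])
  kinds <- day_kinds(track, segments)
  in_cross <- track$date > track$date[entry] & track$date <= track$date[exit]
  stop_days <- sum(in_cross & kinds == "stopover")
  list(total_days = total, travel_days = total - stop_days)
}

#' Paired seasonal comparison
#'
#' Compares per-bird values between seasons with differences taken as
#' autumn minus spring: a paired t test (`method = "t"`), a Wilcoxon
#' signed-rank test whose statistic V is the sum of ranks of positive
#' differences (`"wilcoxon"`), or a sign-flip permutation test of the mean
#' difference (`"permutation"`).
#'
#' @param autumn,spring Equal-length paired per-bird values (n >= 5).
#' @param method One of `"t"`, `"wilcoxon"`, `"permutation"`.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Seed for the permutation draw.
#' @return A list of class `seasonal_comparison`: `statistic_name`
#'   (`"t"` or `"V"`), `statistic`, `n`, `p_value`, `method`.
#' @export
#' @examples
#' seasonal_comparison(2:20, 1:19, method = "wilcoxon")$statistic  # V = 190
seasonal_comparison <- function(autumn, spring,
                                method = c("t", "wilcoxon", "permutation"),
                                n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(autumn) == length(spring))
  n <- length(autumn)
  if (n < 5L) stop("need at least 5 pairs")
  d <- autumn - spring
  if (method == "t") {
    if (stats::sd(d) == 0) stop("zero variance of paired differences")
    ht <- stats::t.test(autumn, spring, paired = TRUE)
    res <- list(statistic_name = "t", statistic = unname(ht$statistic),
                n = n, p_value = ht$p.value, method = "parametric")
  } else if (method == "wilcoxon") {
    if (all(d == 0)) stop("all paired differences are zero")
    # ties/zeros force the normal approximation; the statistic is unaffected
    ht <- suppressWarnings(stats::wilcox.test(autumn, spring, paired = TRUE))
    res <- list(statistic_name = "V", statistic = unname(ht$statistic),
                n = n, p_value = ht$p.value, method = "parametric")
  } else {
    if (stats::sd(d) == 0) stop("zero variance of paired differences")
    obs <- mean(d)
    set.seed(derive_seed(seed, 23L))
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    perm <- as.numeric(flips %*% d) / n
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    res <- list(statistic_name = "t", statistic = obs, n = n, p_value = p,
                method = "permutation")
  }
  class(res) <- "seasonal_comparison"
  res
}
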