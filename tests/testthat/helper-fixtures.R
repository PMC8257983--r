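# Fixtures built in code: tiny scenarios, hand-made wind fields and
# independent oracles used across the test files.

# A small wind field with analytically known node values, built directly
# (not via the scenario generator) so it can serve as an independent input.
make_field <- function(fun_u, fun_v,
                       lon = seq(-10, 30, by = 5), lat = seq(0, 70, by = 5),
                       level = c(1000, 925, 850, 700, 600, 500),
                       dates = seq(as.Date("2020-05-01"), as.Date("2020-06-15"),
                                   by = 1)) {
  time <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  g <- expand.grid(lon = lon, lat = lat, level = level,
                   time = as.numeric(time), KEEP.OUT.ATTRS = FALSE)
  td <- (g$time - as.numeric(time[1])) / 86400
  dims <- c(length(lon), length(lat), length(level), length(time))
  wind_field(lon, lat, level, time,
             array(fun_u(g$lon, g$lat, g$level, td), dims),
             array(fun_v(g$lon, g$lat, g$level, td), dims))
}

constant_field <- function(u, v, ...) {
  make_field(function(lon, lat, lev, td) rep(u, length(lon)),
             function(lon, lat, lev, td) rep(v, length(lon)), ...)
}

# Independent weighted-corner interpolation oracle: explicit product weights
# over the 16 corners (linear in log-pressure on the level axis).
corner_oracle <- function(field, lon, lat, level, time) {
  locate <- function(x, ax, trans = identity) {
    i <- findInterval(x, ax, rightmost.closed = TRUE, all.inside = TRUE)
    list(i = i, w = (trans(x) - trans(ax[i])) / (trans(ax[i + 1]) - trans(ax[i])))
  }
  lx <- locate(lon, field$lon)
  ly <- locate(lat, field$lat)
  ll <- locate(level, field$level, log)
  lt <- locate(as.numeric(as.POSIXct(time, tz = "UTC")),
               as.numeric(field$time))
  out_u <- 0; out_v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dl in 0:1) for (dt in 0:1) {
    w <- (if (dx) lx$w else 1 - lx$w) * (if (dy) ly$w else 1 - ly$w) *
      (if (dl) ll$w else 1 - ll$w) * (if (dt) lt$w else 1 - lt$w)
    out_u <- out_u + w * field$u[lx$i + dx, ly$i + dy, ll$i + dl, lt$i + dt]
    out_v <- out_v + w * field$v[lx$i + dx, ly$i + dy, ll$i + dl, lt$i + dt]
  }
  c(u = out_u, v = out_v)
}

# Plain haversine, written out independently of the package's wrapper.
plain_haversine <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# A hand-made per-bird track: contiguous dates, given positions.
make_track <- function(dates, lat, lon, season = "autumn", bird_id = "b1") {
  data.frame(bird_id = bird_id, season = season, date = dates,
             lat = lat, lon = lon, lat_valid = !is.na(lat))
}

# A hand-made segment table from (kind, start, end) triples.
make_segments <- function(kind, start, end, track,
                          is_initial = rep(FALSE, length(kind))) {
  segs <- data.frame(kind = kind, start_date = as.Date(start),
                     end_date = as.Date(end))
  segs$duration <- as.integer(segs$end_date - segs$start_date) + 1L
  segs$centroid_lat <- vapply(seq_len(nrow(segs)), function(i) {
    mean(track$lat[track$date >= segs$start_date[i] &
                     track$date <= segs$end_date[i]])
  }, numeric(1))
  segs$centroid_lon <- vapply(seq_len(nrow(segs)), function(i) {
    mean(track$lon[track$date >= segs$start_date[i] &
                     track$date <= segs$end_date[i]])
  }, numeric(1))
  segs$is_initial <- is_initial
  segs
}

# A 42-day scripted autumn migration with exactly 20 travel and 22 stopover
# days between departure (15 Aug) and arrival (26 Sep), plus flanking
# residencies, used for date-convention and summary arithmetic tests.
table_style_autumn_track <- function() {
  dates <- seq(as.Date("2019-08-15"), as.Date("2019-09-30"), by = 1)
  n <- length(dates)
  lat <- numeric(n); lon <- rep(15, n)
  lat[1] <- 65
  kinds <- character(n)
  stop1 <- dates >= as.Date("2019-08-18") & dates <= as.Date("2019-09-08")
  for (i in 2:n) {
    if (stop1[i] || dates[i] >= as.Date("2019-09-26")) {
      lat[i] <- lat[i - 1]        # stationary: stopover or terminal residency
    } else {
      lat[i] <- lat[i - 1] - 2.5  # travel day
    }
  }
  tr <- make_track(dates, lat, lon, season = "autumn")
  segs <- make_segments(
    kind = c("travel", "stopover", "travel", "stopover"),
    start = c("2019-08-15", "2019-08-18", "2019-09-09", "2019-09-26"),
    end = c("2019-08-17", "2019-09-08", "2019-09-25", "2019-09-30"),
    track = tr)
  list(track = tr, segments = segs)
}
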