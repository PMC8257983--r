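test_that("ISA inversion matches reference altitudes and is monotone", {
  expect_equal(pressure_to_altitude(1013.25), 0, tolerance = 1e-9)
  expect_equal(pressure_to_altitude(500), 5574, tolerance = 10 / 5574)
  expect_equal(pressure_to_altitude(700), 3012, tolerance = 10 / 3012)
  p <- seq(1100, 10, by = -5)
  expect_true(all(diff(pressure_to_altitude(p)) > 0))
  expect_error(pressure_to_altitude(-5), "positive")
  expect_error(pressure_to_altitude(5), "\\[10, 1100\\]")
})

test_that("tailwind decomposition preserves magnitude and matches a rotation oracle", {
  expect_equal(tailwind_component(0, 10, 0), data.frame(tailwind = 10, crosswind = 0))
  tc <- tailwind_component(10, 0, 0)
  expect_equal(tc$tailwind, 0)
  expect_equal(tc$crosswind, 10)
  for (az in seq(0, 359, by = 7.3)) {
    tc <- tailwind_component(3, 4, az)
    a <- az * pi / 180
    oracle <- matrix(c(sin(a), cos(a), cos(a), -sin(a)), 2, byrow = TRUE) %*% c(3, 4)
    expect_equal(tc$tailwind, oracle[1], tolerance = 1e-12)
    expect_equal(tc$crosswind, oracle[2], tolerance = 1e-12)
    expect_equal(tc$tailwind^2 + tc$crosswind^2, 25, tolerance = 1e-6)
  }
  expect_error(tailwind_component(1, 1, 360), "azimuth")
})

test_that("wind sampling interpolates exactly at nodes and linearly between", {
  fld <- make_field(function(lon, lat, lev, td) 2 * lon + 0.5 * lat,
                    function(lon, lat, lev, td) 0.1 * lev + td)
  # exact node values
  w <- sample_wind(fld, fld$lon[2], fld$lat[3], fld$level[4], fld$time[5])
  expect_equal(w$u, 2 * fld$lon[2] + 0.5 * fld$lat[3], tolerance = 1e-12)
  expect_equal(w$v, 0.1 * fld$level[4] + 4, tolerance = 1e-12)
  # midpoint of two nodes on a linear-axis field: arithmetic mean
  mid_lon <- (fld$lon[2] + fld$lon[3]) / 2
  wm <- sample_wind(fld, mid_lon, fld$lat[3], fld$level[4], fld$time[5])
  expect_equal(wm$u, 2 * mid_lon + 0.5 * fld$lat[3], tolerance = 1e-12)
  # random in-hull queries match the weighted-corner oracle
  set.seed(7)
  for (q in 1:200) {
    lon <- runif(1, min(fld$lon), max(fld$lon))
    lat <- runif(1, min(fld$lat), max(fld$lat))
    lev <- runif(1, min(fld$level), max(fld$level))
    tm <- as.POSIXct(runif(1, as.numeric(min(fld$time)),
                           as.numeric(max(fld$time))),
                     origin = "1970-01-01", tz = "UTC")
    w <- sample_wind(fld, lon, lat, lev, tm)
    o <- corner_oracle(fld, lon, lat, lev, tm)
    expect_equal(w$u, unname(o["u"]), tolerance = 1e-9)
    expect_equal(w$v, unname(o["v"]), tolerance = 1e-9)
  }
  expect_error(sample_wind(fld, 1000, 10, 700, fld$time[1]), "hull")
  expect_error(sample_wind(fld, 10, 10, 700,
                           min(fld$time) - 86400 * 30), "hull")
})

test_that("tailwind profiles compose sampling with decomposition", {
  fld <- constant_field(0, 8)
  prof <- tailwind_profile(fld, 40, 10, 35, 10, as.Date("2020-05-10"))
  expect_equal(prof$tailwind, rep(-8, 6), tolerance = 1e-9)  # southbound, headwind
  expect_true(all(diff(prof$altitude) > 0))                  # decreasing pressure
  expect_equal(prof$tailwind^2 + prof$crosswind^2,
               prof$u^2 + prof$v^2, tolerance = 1e-6)
  # planted 700-hPa jet peaks the profile at 700
  jet <- make_field(function(lon, lat, lev, td) rep(0, length(lon)),
                    function(lon, lat, lev, td) 10 * exp(-(lev - 700)^2 / 1e4))
  prof2 <- tailwind_profile(jet, 30, 10, 35, 10, as.Date("2020-05-10"))
  expect_equal(prof2$level[which.max(prof2$tailwind)], 700)
  # composition identity: manual sample_wind + tailwind_component
  mid <- gc_midpoint(30, 10, 35, 10)
  az <- initial_bearing(30, 10, 35, 10)
  w <- sample_wind(jet, mid[1, "lon"], mid[1, "lat"], 850,
                   as.POSIXct("2020-05-10 12:00:00", tz = "UTC"))
  tc <- tailwind_component(w$u, w$v, az)
  expect_equal(prof2$tailwind[prof2$level == 850], tc$tailwind, tolerance = 1e-12)
})

test_that("flight-level selection maximises tailwind with low-altitude tie-break", {
  prof <- data.frame(level = c(1000, 925, 850, 700, 600, 500),
                     altitude = pressure_to_altitude(c(1000, 925, 850, 700, 600, 500)),
                     tailwind = rep(4, 6), crosswind = 0)
  sel <- select_flight_level(prof)
  expect_equal(sel$level, 1000)             # constant profile: lowest altitude
  prof$tailwind <- c(1, 2, 3, 9, 3, 2)
  expect_equal(select_flight_level(prof)$level, 700)
  expect_equal(select_flight_level(prof)$altitude, 3012, tolerance = 10 / 3012)
  # allowed range excluding the jet: boundary level with max tailwind within range
  sel2 <- select_flight_level(prof, allowed_range = c(1000, 850))
  expect_equal(sel2$level, 850)
  expect_error(select_flight_level(prof, allowed_range = c(300, 400)), "range")
  # exhaustive-scan oracle: selected tailwind is never below any allowed level
  set.seed(8)
  for (r in 1:100) {
    prof$tailwind <- rnorm(6)
    sel3 <- select_flight_level(prof)
    expect_equal(sel3$tailwind, max(prof$tailwind))
  }
})

test_that("track annotation builds steps from travel-day pairs only", {
  fld <- constant_field(0, -8, lat = seq(0, 70, 5), dates = seq(as.Date("2019-08-01"), as.Date("2019-10-31"), 1))
  # all-stopover track: no steps
  dates <- seq(as.Date("2019-08-20"), by = 1, length.out = 8)
  still <- make_track(dates, rep(40, 8), rep(5, 8))
  segs <- make_segments("stopover", "2019-08-20", "2019-08-27", still)
  expect_equal(nrow(annotate_track(still, segs, fld)), 0L)
  # due-south track in a constant northerly wind: mean tailwind 8
  south <- make_track(dates, seq(60, by = -3, length.out = 8), rep(5, 8))
  segs_s <- make_segments("travel", "2019-08-20", "2019-08-27", south)
  steps <- annotate_track(south, segs_s, fld)
  expect_equal(nrow(steps), 7L)
  expect_equal(steps$tailwind, rep(8, 7), tolerance = 1e-6)
  expect_equal(steps$tailwind_over_airspeed, rep(8 / 10.6, 7), tolerance = 1e-6)
  # stopover days in the middle break the step sequence
  segs_m <- make_segments(c("travel", "stopover", "travel"),
                          c("2019-08-20", "2019-08-23", "2019-08-26"),
                          c("2019-08-22", "2019-08-25", "2019-08-27"), south)
  steps_m <- annotate_track(south, segs_m, fld)
  expect_equal(nrow(steps_m), 3L)   # pairs (20,21),(21,22),(26,27)
  expect_true(!any(steps_m$date %in% as.Date(c("2019-08-23", "2019-08-24",
                                               "2019-08-25"))))
})

test_that("annotation is invariant to level storage order and recovers seasonal sign", {
  dates <- seq(as.Date("2020-05-10"), by = 1, length.out = 6)
  north <- make_track(dates, seq(20, by = 4, length.out = 6), rep(10, 6),
                      season = "spring")
  segs <- make_segments("travel", "2020-05-10", "2020-05-15", north)
  fld <- make_field(function(lon, lat, lev, td) 0.2 * lat,
                    function(lon, lat, lev, td) 5 + 10 * exp(-(lev - 700)^2 / 5000))
  rev_fld <- wind_field(fld$lon, fld$lat, rev(fld$level), fld$time,
                        fld$u[, , rev(seq_along(fld$level)), , drop = FALSE],
                        fld$v[, , rev(seq_along(fld$level)), , drop = FALSE])
  s1 <- annotate_track(north, segs, fld)
  s2 <- annotate_track(north, segs, rev_fld)
  expect_equal(s1, s2)
  expect_equal(unique(s1$level), 700)
  # per-step tailwind matches the closed form of the field at the midpoint
  expect_equal(s1$tailwind,
               (0.2 * s1$mid_lat) * sin(s1$azimuth * pi / 180) +
                 15 * cos(s1$azimuth * pi / 180), tolerance = 1e-6)
})

test_that("seasonal tailwind contrast of the default scenarios has the planted sign", {
  means <- sapply(list(autumn_scenario(n_birds = 4), spring_scenario(n_birds = 4)),
                  function(sc) {
    sim <- simulate_tracks(sc, seed = 71)
    fld <- simulate_wind_field(sc)
    tws <- c()
    for (tr in split_birds(sim$observed)) {
      segs <- segment_track(tr)
      steps <- annotate_track(tr, segs, fld)
      tws <- c(tws, steps$tailwind)
    }
    mean(tws)
  })
  expect_gt(means[2], means[1])   # spring winds planted more supportive
  expect_gt(means[1], 0)
})
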