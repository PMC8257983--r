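test_that("zero-noise observations equal true positions and runs are deterministic", {
  sc <- autumn_scenario(n_birds = 3, departure_jitter_sd = 0,
                        initial_stopover_prob = 1,
                        noise_sd_lat = 0, noise_sd_lon = 0, equinox_window = 0)
  sim1 <- simulate_tracks(sc, seed = 11)
  expect_equal(sim1$observed$lat, sim1$true$lat)
  expect_equal(sim1$observed$lon, sim1$true$lon)
  sim2 <- simulate_tracks(sc, seed = 11)
  expect_identical(sim1, sim2)
  sim3 <- simulate_tracks(sc, seed = 12)
  sc_noisy <- autumn_scenario(n_birds = 3)
  expect_false(identical(simulate_tracks(sc_noisy, 1)$observed$lat,
                         simulate_tracks(sc_noisy, 2)$observed$lat))
  expect_identical(sim1$script, sim3$script)  # schedule unchanged without jitter
})

test_that("observation noise has the configured magnitude over ~500 days", {
  legs <- data.frame(lat = 30, lon = 10, travel_days = 2, stopover_days = 500)
  sc <- swift_scenario(c(lat = 32, lon = 10), c(lat = 30, lon = 10), legs,
                       season = "autumn", departure_date = "2019-01-05",
                       n_birds = 1, noise_sd_lat = 1.0, noise_sd_lon = 0.5,
                       equinox_window = 0, arrival_residency_days = 0)
  sim <- simulate_tracks(sc, seed = 5)
  dlat <- sim$observed$lat - sim$true$lat
  dlon <- sim$observed$lon - sim$true$lon
  expect_gt(sd(dlat), 0.8); expect_lt(sd(dlat), 1.2)
  expect_gt(sd(dlon), 0.4); expect_lt(sd(dlon), 0.6)
})

test_that("true-track leg lengths sum to the waypoint polyline length", {
  for (make in list(autumn_scenario, spring_scenario)) {
    sc <- make(n_birds = 1, departure_jitter_sd = 0)
    sc$noise_sd_lat <- 0; sc$noise_sd_lon <- 0
    sim <- simulate_tracks(sc, seed = 2)
    tt <- split_birds(sim$true)[[1]]
    from <- if (sc$season == "autumn") sc$breeding_site else sc$wintering_site
    way <- rbind(c(from[["lat"]], from[["lon"]]),
                 as.matrix(sc$legs[, c("lat", "lon")]))
    polyline <- sum(gc_distance_km(way[-nrow(way), 1], way[-nrow(way), 2],
                                   way[-1, 1], way[-1, 2]))
    expect_equal(route_length(tt), polyline, tolerance = 1e-3)
  }
})

test_that("equinox flagging hits exactly the dates within the window", {
  sc <- autumn_scenario(n_birds = 1, departure_jitter_sd = 0, equinox_window = 10)
  sim <- simulate_tracks(sc, seed = 3)
  obs <- split_birds(sim$observed)[[1]]
  expected <- obs$date >= as.Date("2019-09-12") & obs$date <= as.Date("2019-10-02")
  expect_equal(!obs$lat_valid, expected)
  expect_true(all(is.na(obs$lat[expected])))
  expect_true(all(!is.na(obs$lon)))  # longitudes never masked
})

test_that("scenario validation rejects degenerate schedules", {
  legs0 <- data.frame(lat = 5, lon = 5, travel_days = 0, stopover_days = 0)
  expect_error(swift_scenario(c(lat = 5, lon = 5), c(lat = 5, lon = 5), legs0,
                              season = "autumn", departure_date = "2019-08-01"),
               "zero-length")
  legs_same <- data.frame(lat = 5, lon = 5, travel_days = 3, stopover_days = 0)
  expect_error(swift_scenario(c(lat = 5, lon = 5), c(lat = 5, lon = 5), legs_same,
                              season = "autumn", departure_date = "2019-08-01"),
               "identical")
  legs_neg <- data.frame(lat = 5, lon = 5, travel_days = -1, stopover_days = 0)
  expect_error(swift_scenario(c(lat = 10, lon = 5), c(lat = 5, lon = 5), legs_neg,
                              season = "autumn", departure_date = "2019-08-01"),
               ">= 0")
})

test_that("constant wind config fills every node with the base wind", {
  sc <- spring_scenario(n_birds = 1)
  sc$wind <- wind_params(base_u = 5, base_v = 0)
  fld <- simulate_wind_field(sc)
  expect_true(all(fld$u == 5))
  expect_true(all(fld$v == 0))
})

test_that("a planted jet maximises wind speed at its level", {
  sc <- spring_scenario(n_birds = 1)
  sc$wind <- wind_params(base_u = 2, base_v = 1, jet_u = 6, jet_v = 3,
                         jet_level = 700, jet_width = 80)
  fld <- simulate_wind_field(sc)
  spd <- sqrt(fld$u^2 + fld$v^2)
  by_level <- apply(spd, 3, mean)
  expect_equal(fld$level[which.max(by_level)], 700)
  # every node at 700 beats the same node at any other level
  i700 <- which(fld$level == 700)
  for (k in seq_along(fld$level)) {
    if (k != i700) expect_true(all(spd[, , i700, ] >= spd[, , k, ]))
  }
  expect_error(simulate_wind_field(sc, default_wind_grid(sc, levels = c(1000, 850, 500))),
               "jet_level")
})

test_that("a temporal ramp shifts mean wind by exactly rate times days", {
  sc <- spring_scenario(n_birds = 1)
  k <- 0.7
  sc$wind <- wind_params(base_v = 1, ramp_v = k)
  fld <- simulate_wind_field(sc)
  d <- 9
  v1 <- mean(fld$v[, , , 1]); v2 <- mean(fld$v[, , , 1 + d])
  expect_equal(v2 - v1, k * d, tolerance = 1e-12)
})

test_that("grid nodes match the generator closed form to 1e-9", {
  sc <- spring_scenario(n_birds = 1)
  fld <- simulate_wind_field(sc)
  set.seed(42)
  for (q in 1:50) {
    i <- sample(length(fld$lon), 1); j <- sample(length(fld$lat), 1)
    k <- sample(length(fld$level), 1); l <- sample(length(fld$time), 1)
    w <- wind_field_value(sc$wind, fld$lon[i], fld$lat[j], fld$level[k],
                          fld$time[l], origin = sc$departure_date)
    expect_equal(fld$u[i, j, k, l], w$u, tolerance = 1e-9)
    expect_equal(fld$v[i, j, k, l], w$v, tolerance = 1e-9)
  }
  narrow <- default_wind_grid(sc)
  narrow$lat <- narrow$lat[narrow$lat < 40]
  expect_error(simulate_wind_field(sc, narrow), "cover")
})

test_that("light series reproduces equinox symmetry and polar day", {
  ls <- simulate_light_series(0, 0, "2020-03-20", "2020-03-20",
                              interval_min = 10, zenith = 90)
  tw <- detect_twilights(ls, geolocation_config(zenith = 90))
  expect_equal(nrow(tw), 2L)
  mins <- as.numeric(tw$timestamp - as.POSIXct("2020-03-20", tz = "UTC"),
                     units = "mins")
  # transitions near 06:00 / 18:00 UTC (the equation of time shifts both)
  expect_lt(abs(mins[1] - 360), 10 + abs(solar_ephemeris(ls$timestamp_utc[1])$eq_time))
  expect_lt(abs(mins[2] - 1080), 10 + abs(solar_ephemeris(ls$timestamp_utc[1])$eq_time))
  polar <- simulate_light_series(67, 21, "2020-06-20", "2020-06-21")
  expect_true(all(polar$light == max(polar$light)))  # no night
  dark <- simulate_light_series(-80, 0, "2020-06-20", "2020-06-21")
  expect_true(all(dark$light == min(dark$light)))
  expect_error(simulate_light_series(0, 0, "2020-01-01", "2020-01-02",
                                     interval_min = 30), "interval")
  expect_error(simulate_light_series(0, 0, "2020-01-01", "2020-01-02",
                                     zenith = 89), "zenith")
})

test_that("track and wind CSV round trips are lossless", {
  sim <- simulate_tracks(spring_scenario(n_birds = 2), seed = 8)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$observed, p)
  back <- read_tracks(p)
  expect_equal(back$lat, sim$observed$lat)
  expect_equal(back$date, sim$observed$date)
  expect_equal(back$lat_valid, sim$observed$lat_valid)

  fld <- constant_field(3, -2, lon = c(0, 5), lat = c(10, 15),
                        level = c(1000, 500),
                        dates = as.Date("2020-05-01") + 0:1)
  pw <- withr::local_tempfile(fileext = ".csv")
  write_wind_field(fld, pw)
  fld2 <- read_wind_field(pw)
  expect_equal(fld2$u, fld$u)
  expect_equal(fld2$level, fld$level)
  expect_equal(as.numeric(fld2$time), as.numeric(fld$time))

  ls <- simulate_light_series(10, 10, "2020-05-01", "2020-05-01")
  pl <- withr::local_tempfile(fileext = ".csv")
  write_light_series(ls, pl)
  ls2 <- read_light_series(pl)
  expect_equal(ls2$light, ls$light)
  expect_equal(as.numeric(ls2$timestamp_utc), as.numeric(ls$timestamp_utc))
})
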