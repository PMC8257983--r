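test_that("solar ephemeris matches standard values", {
  expect_lt(abs(solar_ephemeris(as.Date("2020-03-20"))$declination), 0.6)
  expect_equal(solar_ephemeris(as.Date("2020-06-21"))$declination, 23.44,
               tolerance = 0.3 / 23.44)
  expect_lt(abs(solar_ephemeris(as.Date("2020-04-15"))$eq_time), 2)
  eph <- solar_ephemeris(as.Date("2020-01-01") + 0:364)
  expect_true(all(abs(eph$declination) <= 23.47))
  expect_true(all(abs(eph$eq_time) <= 17))
  expect_error(solar_ephemeris(as.POSIXct("1850-01-01", tz = "UTC")), "years")
})

test_that("twilight detection finds interpolated threshold crossings", {
  # synthetic step curve, one up and one down crossing per day for 10 days
  ls <- simulate_light_series(20, 0, "2020-05-01", "2020-05-10",
                              interval_min = 10)
  tw <- detect_twilights(ls, geolocation_config())
  expect_equal(nrow(tw), 20L)
  expect_true(all(tw$kind[seq(1, 19, 2)] == "sunrise"))
  expect_true(all(tw$kind[seq(2, 20, 2)] == "sunset"))
  expect_true(all(diff(as.numeric(tw$timestamp)) > 0))
  # constant light below threshold: no events
  flat <- data.frame(
    timestamp_utc = as.POSIXct("2020-05-01", tz = "UTC") + (0:200) * 600,
    light = 0)
  expect_equal(nrow(detect_twilights(flat, geolocation_config())), 0L)
  expect_error(detect_twilights(flat[0, ], geolocation_config()), "empty")
  # round trip: event times match the generator's crossing times within one
  # sampling interval
  truth_cross <- function(lat, lon, date, zenith) {
    tt <- seq(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"),
              by = 30, length.out = 2880)
    e <- solar_elevation(tt, lat, lon)
    up <- which(e[-1] > (90 - zenith) & e[-length(e)] <= (90 - zenith))[1]
    tt[up]
  }
  sr_true <- truth_cross(20, 0, "2020-05-03", 93)
  sr_est <- tw$timestamp[tw$kind == "sunrise"][3]
  expect_lt(abs(as.numeric(sr_est - sr_true, units = "mins")), 10)
})

test_that("twilight pairs geolocate by solar noon and day length", {
  cfg <- geolocation_config(zenith = 90)
  # 06:00-18:00 UTC on an equinox day: longitude near 0, latitude unknown
  pos <- twilight_to_position(as.POSIXct("2020-03-20 06:00:00", tz = "UTC"),
                              as.POSIXct("2020-03-20 18:00:00", tz = "UTC"),
                              cfg)
  expect_lt(abs(pos$lon), 2.5)   # eq-of-time correction keeps it near zero
  expect_false(pos$lat_valid)
  expect_true(is.na(pos$lat))
  # solar noon at 11:00 UTC in mid April (eq of time ~ 0): lon = +15 E
  pos2 <- twilight_to_position(as.POSIXct("2020-04-15 04:00:00", tz = "UTC"),
                               as.POSIXct("2020-04-15 18:00:00", tz = "UTC"),
                               cfg)
  expect_equal(pos2$lon, 15, tolerance = 0.6 / 15)
  expect_error(twilight_to_position(as.POSIXct("2020-04-15 18:00:00", tz = "UTC"),
                                    as.POSIXct("2020-04-15 04:00:00", tz = "UTC"),
                                    cfg),
               "sunset before sunrise")
})

test_that("latitude from day length matches a brute-force scan of the sunrise equation", {
  # 15-h day at the June solstice, zenith 90
  delta <- solar_ephemeris(as.Date("2020-06-21"))$declination
  for (day_h in c(10, 13.5, 15)) {
    H <- day_h * 15 / 2
    phi_grid <- seq(-90, 90, by = 0.01)
    resid <- abs(sin(phi_grid * pi / 180) * sin(delta * pi / 180) +
                   cos(phi_grid * pi / 180) * cos(delta * pi / 180) *
                     cos(H * pi / 180) - cos(90 * pi / 180))
    phi_oracle <- phi_grid[which.min(resid)]
    phi <- swiftmigr:::latitude_from_daylength(H, delta, 90)
    expect_equal(phi, phi_oracle, tolerance = 0.02)
  }
})

test_that("daily averaging is stationary-consistent and circular in longitude", {
  expect_equal(circular_mean_lon(c(179.5, -179.5)), 180)
  expect_equal(circular_mean_lon(c(10, 20)), 15)
  cfg <- geolocation_config()
  ls <- simulate_light_series(45, 10, "2020-05-01", "2020-05-05",
                              interval_min = 1)
  tw <- detect_twilights(ls, cfg)
  pos <- daily_positions(tw, cfg)
  expect_true(all(abs(diff(pos$lat)) < 0.2))   # stationary site, constant fixes
  expect_true(all(abs(diff(pos$lon)) < 0.1))
  # interior day averages equal the arithmetic mean of that day's pair fixes
  day_fix <- twilight_to_position(tw$timestamp[3], tw$timestamp[4], cfg)
  night1 <- swiftmigr:::fix_from_pair(tw$timestamp[2], "sunset",
                                      tw$timestamp[3], cfg)
  night2 <- swiftmigr:::fix_from_pair(tw$timestamp[4], "sunset",
                                      tw$timestamp[5], cfg)
  d2 <- pos[2, ]
  contrib <- c(day_fix$lat, night1$lat, night2$lat)
  # the day's averaged latitude lies within the span of its contributing fixes
  expect_gte(d2$lat, min(contrib) - 1e-9)
  expect_lte(d2$lat, max(contrib) + 1e-9)
})

test_that("equinox flagging follows the calendar window", {
  dates <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = 1)
  tr <- make_track(dates, rep(40, length(dates)), rep(0, length(dates)))
  fl <- flag_equinox(tr, 10)
  expect_equal(sum(!fl$lat_valid), 2 * (2 * 10 + 1))
  flagged <- fl$date[!fl$lat_valid]
  expect_true(all(flagged >= as.Date("2019-03-10") & flagged <= as.Date("2019-04-01") |
                    flagged >= as.Date("2019-09-12") & flagged <= as.Date("2019-10-02")))
  # mid-winter track untouched
  wdates <- seq(as.Date("2019-12-01"), as.Date("2020-01-31"), by = 1)
  wtr <- make_track(wdates, rep(40, length(wdates)), rep(0, length(wdates)))
  expect_identical(flag_equinox(wtr, 10)$lat, wtr$lat)
  expect_error(flag_equinox(wtr, -1), ">= 0")
})

test_that("noise-free round trip recovers sites within 0.5 deg lat / 0.2 deg lon", {
  cfg <- geolocation_config(zenith = 93)
  for (la in seq(0, 60, 15)) {
    ls <- simulate_light_series(la, 25, "2020-05-01", "2020-05-04",
                                interval_min = 1, zenith = 93)
    pos <- daily_positions(detect_twilights(ls, cfg), cfg)
    expect_true(all(pos$lat_valid))
    expect_lt(max(abs(pos$lat - la)), 0.5)         # every single day
    expect_lt(abs(circular_mean_lon(pos$lon) - 25), 0.2)   # site estimate
  }
})

test_that("longitude stays unbiased inside the equinox window", {
  cfg <- geolocation_config()
  ls <- simulate_light_series(40, -5, "2020-03-15", "2020-03-25",
                              interval_min = 1)
  pos <- daily_positions(detect_twilights(ls, cfg), cfg)
  expect_true(all(!pos$lat_valid))             # all inside the window
  expect_lt(abs(mean(wrap_lon(pos$lon - (-5)))), 0.1)
})

test_that("latitude error grows as declination shrinks on jittered series", {
  cfg <- geolocation_config(zenith = 93, equinox_window = 0)
  lat_err_sd <- function(date, seed) {
    ls <- simulate_light_series(45, 0, date, as.Date(date) + 14,
                                interval_min = 1)
    tw <- detect_twilights(ls, cfg)
    set.seed(seed)
    tw$timestamp <- tw$timestamp + rnorm(nrow(tw), 0, 120)  # 2-min jitter
    tw <- tw[order(tw$timestamp), ]
    pos <- daily_positions(tw, cfg)
    stats::sd(pos$lat, na.rm = TRUE)
  }
  far <- lat_err_sd("2020-05-20", 1)    # |declination| ~ 20
  near <- lat_err_sd("2020-03-25", 1)   # |declination| ~ 2-7
  expect_gt(near, far)
})
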