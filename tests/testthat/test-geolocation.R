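make_calib <- function(a0 = threshold_elevation(light_model(), 2)) {
  structure(
    list(
      a0 = a0, threshold = 2,
      window = as.Date(c("2009-07-01", "2009-07-11")),
      reference = c(lat = 56, lon = 14.5), n_events = 20
    ),
    class = "calibration_model"
  )
}

test_that("longitude from noon inverts the 15 degrees-per-hour relation", {
  # Greenwich: noon pair symmetric around 12:00 UTC on a day with eqtime ~ 0
  # (mid-April); the equation of time is applied internally, so pick instants
  # and compare against the direct formula
  sr <- as.POSIXct("2009-04-15 06:00:00", tz = "UTC")
  ss <- as.POSIXct("2009-04-15 18:00:00", tz = "UTC")
  lam <- longitude_from_noon(sr, ss)
  eqt <- solar_state(as.POSIXct("2009-04-15 12:00:00", tz = "UTC"))$eqtime
  expect_equal(lam, 15 * (-eqt / 60), tolerance = 0.05)

  # local noon at 11:02 UTC with eqtime removed corresponds to 14.5E
  mid_target <- as.POSIXct("2009-04-15 11:02:00", tz = "UTC") -
    60 * solar_state(as.POSIXct("2009-04-15 11:02:00", tz = "UTC"))$eqtime
  lam2 <- longitude_from_noon(mid_target - 6 * 3600, mid_target + 6 * 3600)
  expect_equal(lam2, 14.5, tolerance = 0.1 / 14.5)

  expect_error(
    longitude_from_noon(sr, ss + 86400 * 2),
    "more than 24 h"
  )
})

test_that("fixed logger at the colony recovers its longitude to 0.2 degrees", {
  trk <- stationary_track(56, 14.5, "2009-07-01", 10)
  s <- simulate_light(trk, light_model(noise_sd = 0), seed = 1)
  cal <- calibrate(s, 56, 14.5, c(as.Date("2009-07-01"), as.Date("2009-07-11")))
  pos <- locate_positions(s, cal)
  expect_lt(abs(median(pos$lon) - 14.5), 0.2)
})

test_that("latitude from day length recovers a mid-latitude site and flags degeneracies", {
  m <- light_model(noise_sd = 0)
  a0 <- threshold_elevation(m, 2)
  # 43N in late July (simulator ground truth via the elevation-scan oracle)
  dl <- oracle_day_length("2009-07-27", 43, -31, a0)
  r <- latitude_from_daylength(dl, "2009-07-27", a0)
  expect_true(r$valid)
  expect_equal(r$lat, 43, tolerance = 1 / 43)

  # 24-hour day: no solution, polar
  r24 <- latitude_from_daylength(24, "2009-12-21", a0)
  expect_false(r24$valid)
  expect_equal(r24$reason, "polar")

  # equinox: day length carries no latitude information
  req <- latitude_from_daylength(12.9, "2009-09-22", a0)
  expect_false(req$valid)
  expect_equal(req$reason, "equinox")

  expect_error(latitude_from_daylength(25, "2009-07-27", a0), "0, 24")
})

test_that("polar-day longitudes are recovered at elevated thresholds with biased latitude", {
  m <- light_model(noise_sd = 0)
  cal <- make_calib()
  trk <- stationary_track(-65, 100, "2009-12-10", 10)
  s <- simulate_light(trk, m, seed = 2)
  ev_std <- detect_twilights(s, 2)
  expect_equal(nrow(ev_std), 0) # standard threshold defeated by polar day
  pos <- locate_positions(s, cal)
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$lat_biased))
  expect_false(any(pos$lat_valid))
  lon <- pos$lon
  expect_lt(max(abs(lon - 100)), 1)
  # the apparent latitude, where solvable, is biased equatorward (north of -65)
  expect_true(all(pos$lat > -65, na.rm = TRUE))
})

test_that("deep polar day yields no positions at any threshold", {
  cal <- make_calib()
  trk <- stationary_track(-70, 0, "2009-12-18", 6)
  s <- simulate_light(trk, light_model(noise_sd = 0), seed = 1)
  pos <- locate_positions(s, cal)
  expect_equal(nrow(pos), 0)
})

test_that("elevated thresholds are a no-op when standard crossings exist", {
  cal <- make_calib()
  trk <- stationary_track(43, -31, "2009-07-20", 6)
  s <- simulate_light(trk, light_model(noise_sd = 0), seed = 1)
  pos_with <- locate_positions(s, cal, elevated_thresholds = c(40, 100))
  pos_without <- locate_positions(s, cal, elevated_thresholds = numeric(0))
  expect_equal(pos_with, pos_without, ignore_attr = TRUE)
  expect_false(any(pos_with$lat_biased))
})

test_that("longitude estimator is essentially unbiased under symmetric light noise", {
  cal <- make_calib()
  trk <- stationary_track(-10, 40, "2009-05-01", 100)
  s <- simulate_light(trk, light_model(noise_sd = 0.5), seed = 17)
  pos <- locate_positions(s, cal)
  expect_gt(nrow(pos), 150)
  expect_lt(abs(mean(pos$lon) - 40), 0.1)
})

test_that("elevated-threshold latitude bias is always equatorward for southern truth", {
  cal <- make_calib()
  lats <- c(-62, -64, -66)
  for (lat in lats) {
    trk <- stationary_track(lat, 50, "2009-12-05", 8)
    s <- simulate_light(trk, light_model(noise_sd = 0), seed = 3)
    pos <- locate_positions(s, cal)
    biased_lat <- pos$lat[pos$lat_biased & !is.na(pos$lat)]
    if (length(biased_lat)) expect_true(all(biased_lat > lat))
  }
})
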