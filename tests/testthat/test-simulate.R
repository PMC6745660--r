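test_that("trajectory interpolation matches the closed-form linear oracle", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-11")),
    lat = c(0, 0), lon = c(0, 10)
  )
  sc <- trajectory_scenario(wp, colony = c(56, 14.5))
  tr <- interpolate_trajectory(sc, step_hours = 24)
  t0 <- as.POSIXct("2008-09-01 00:00:00", tz = "UTC")
  t1 <- as.POSIXct("2008-09-11 00:00:00", tz = "UTC")
  expect_equal(tr$lon, oracle_linear_lon(tr$time, t0, t1, 0, 10),
    tolerance = 1e-10
  )
  expect_equal(tr$lat, rep(0, nrow(tr)))
  # one degree per day
  expect_equal(diff(tr$lon), rep(1, nrow(tr) - 1), tolerance = 1e-10)
})

test_that("degenerate segment between identical waypoints stays put", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-11")),
    lat = c(-38, -38), lon = c(65, 65)
  )
  sc <- trajectory_scenario(wp, colony = c(56, 14.5))
  tr <- interpolate_trajectory(sc, step_hours = 6)
  expect_true(all(tr$lat == -38))
  expect_true(all(tr$lon == 65))
})

test_that("interpolation step larger than the shortest waypoint gap errors", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-03", "2008-10-01")),
    lat = c(0, 0, 0), lon = c(0, 2, 10)
  )
  sc <- trajectory_scenario(wp, colony = c(56, 14.5))
  expect_error(interpolate_trajectory(sc, step_hours = 72), "shortest waypoint gap")
})

test_that("scenario validation enforces its invariants", {
  wp_bad_date <- tibble::tibble(
    date = as.Date(c("2008-09-02", "2008-09-01")), lat = c(0, 0), lon = c(0, 1)
  )
  expect_error(
    trajectory_scenario(wp_bad_date, colony = c(56, 14.5)),
    "strictly increasing"
  )
  wp_bad_lat <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-02")), lat = c(0, 95), lon = c(0, 1)
  )
  expect_error(trajectory_scenario(wp_bad_lat, colony = c(56, 14.5)), "-90, 90")
  wp_wrap <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-02")), lat = c(0, 0),
    lon = c(175, -175)
  )
  expect_error(trajectory_scenario(wp_wrap, colony = c(56, 14.5)), "unwrapped")
})

test_that("mean-schedule scenario passes 50S around 1 November", {
  sc <- mean_schedule_scenario(noise = 0)
  tr <- interpolate_trajectory(sc, step_hours = 24)
  on_nov1 <- tr[as.Date(tr$time) == as.Date("2008-11-01"), ]
  expect_equal(on_nov1$lat, -50, tolerance = 1 / 50)
  on_jan1 <- tr[as.Date(tr$time) == as.Date("2009-01-01"), ]
  expect_equal(on_jan1$lon, 71, tolerance = 1 / 71)
})

test_that("scenario files round-trip through YAML", {
  sc <- mean_schedule_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$waypoints, sc$waypoints)
  expect_equal(unname(sc2$colony), unname(sc$colony))
  expect_equal(sc2$noise, sc$noise)
})

test_that("simulated light is reproducible, clipped and monotone in elevation", {
  trk <- stationary_track(56, 14.5, "2009-06-20", 3)
  m <- light_model(noise_sd = 0.5)
  s1 <- simulate_light(trk, m, seed = 11)
  s2 <- simulate_light(trk, m, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_light(trk, m, seed = 12)
  expect_false(identical(s1$light, s3$light))
  expect_true(all(s1$light >= 0 & s1$light <= m$clip_max))
  # noiseless light is monotone in solar elevation
  s0 <- simulate_light(trk, light_model(noise_sd = 0), seed = 1)
  el <- solar_elevation(s0$timestamp, 56, 14.5)
  o <- order(el)
  expect_true(all(diff(s0$light[o]) >= -1e-9))
  # midsummer at 56N: midnight darker than noon
  midnight <- s0$light[format(s0$timestamp, "%H:%M") == "00:00"]
  noon <- s0$light[format(s0$timestamp, "%H:%M") == "11:00"]
  expect_lt(max(midnight), min(noon))
})

test_that("polar-day light at 65S in December never crosses the standard threshold", {
  trk <- stationary_track(-65, 0, "2009-12-15", 10)
  s <- simulate_light(trk, light_model(noise_sd = 0), seed = 1)
  expect_gt(min(s$light), 2)
})

test_that("equatorial light on an equinox crosses a midpoint threshold twice ~12 h apart", {
  # with the transfer located at 0 deg elevation, the half-saturation threshold
  # corresponds to the geometric sunrise/sunset
  m <- light_model(location = 0, noise_sd = 0, interval_min = 5)
  trk <- stationary_track(0, 0, "2009-03-19", 3)
  s <- simulate_light(trk, m, seed = 1)
  ev <- detect_twilights(s, threshold = m$clip_max / 2)
  gaps <- diff(as.numeric(ev$time)) / 3600
  day_gaps <- gaps[seq(1, length(gaps), by = 2)]
  expect_true(all(abs(day_gaps - 12) < 5 / 60 + 0.2))
})

test_that("stationary periods hold latitude and drift longitude at the stated rate", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-09-01", "2008-09-10", "2008-09-20")),
    lat = c(-38, -38, -40), lon = c(60, 64.5, 90)
  )
  sp <- tibble::tibble(
    start = as.Date("2008-09-01"), end = as.Date("2008-09-10"), rate = 0.5
  )
  sc <- trajectory_scenario(wp,
    colony = c(56, 14.5), stationary_periods = sp
  )
  tr <- interpolate_trajectory(sc, step_hours = 24)
  sel <- as.Date(tr$time) <= as.Date("2008-09-10")
  expect_equal(diff(tr$lon[sel]), rep(0.5, sum(sel) - 1), tolerance = 1e-10)
  expect_true(all(tr$lat[sel] == -38))
})

test_that("simulate_light validates its inputs", {
  expect_error(simulate_light(NULL), "empty track")
  short <- stationary_track(0, 0, "2009-03-19", 1, step_hours = 3)
  short <- short[as.numeric(short$time) - as.numeric(short$time[1]) < 3600 * 12, ]
  expect_error(simulate_light(short), "full day")
})
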