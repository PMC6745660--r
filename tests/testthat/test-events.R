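test_that("all mean-schedule events are recovered within 3 days of scenario truth", {
  sc <- mean_schedule_scenario()
  truth <- attr(sc, "truth")
  tr <- simulate_track(sc, seed = 42)
  ev <- detect_events(tr)
  det <- c(
    ev$departure_breeding, ev$natl_furthest_w_date, ev$equator_crossing,
    ev$pass_20e, ev$pass_50s, ev$furthest_e_date,
    ev$antarctic_furthest_w_date, ev$departure_antarctica,
    ev$natl_furthest_w_spring_date, ev$arrival_breeding
  )
  expect_false(any(is.na(det)))
  expect_true(all(abs(as.numeric(det - truth$date)) <= 3))
  expect_equal(ev$furthest_e_lon, 141, tolerance = 2 / 141)
  expect_equal(ev$natl_furthest_w_lon, -31, tolerance = 2 / 31)
  # temporal ordering of the present events
  expect_true(all(diff(as.numeric(det)) >= 0))
  # furthest east is east of the 20E passage by construction of the journey
  expect_gt(ev$furthest_e_lon, 20)
})

test_that("a track truncated in autumn yields missing spring events", {
  sc <- mean_schedule_scenario()
  tr <- simulate_track(sc, seed = 7)
  tr_cut <- tr[tr$date <= as.Date("2008-11-30"), ]
  attr(tr_cut, "colony") <- attr(tr, "colony")
  attr(tr_cut, "label") <- attr(tr, "label")
  class(tr_cut) <- class(tr)
  ev <- detect_events(tr_cut)
  expect_false(is.na(ev$departure_breeding))
  expect_false(is.na(ev$pass_50s))
  expect_true(is.na(ev$departure_antarctica))
  expect_true(is.na(ev$antarctic_furthest_w_date))
  expect_true(is.na(ev$arrival_breeding))
})

test_that("a stationary colony-only track produces no events", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-07-01", "2009-03-01")),
    lat = c(56, 56), lon = c(14.5, 14.5)
  )
  tr <- quick_track(wp, noise = 0.3, seed = 9)
  ev <- detect_events(tr)
  expect_true(is.na(ev$departure_breeding))
  expect_true(is.na(ev$pass_50s))
  expect_true(is.na(ev$arrival_breeding))
})

test_that("event detection is invariant to adding 360 to all longitudes", {
  sc <- mean_schedule_scenario()
  tr <- simulate_track(sc, seed = 5)
  tr2 <- tr
  tr2$lon <- tr2$lon + 360
  ev1 <- detect_events(tr)
  ev2 <- detect_events(tr2)
  expect_equal(ev1$departure_breeding, ev2$departure_breeding)
  expect_equal(ev1$pass_20e, ev2$pass_20e)
  expect_equal(ev1$furthest_e_date, ev2$furthest_e_date)
  expect_equal(ev1$furthest_e_lon, ev2$furthest_e_lon)
  expect_equal(ev1$arrival_breeding, ev2$arrival_breeding)
})

test_that("planted plateau is recovered as one stopover with its rate and duration", {
  sc <- plateau_scenario(fast = 2.5, slow = 0.3, plateau_days = 12)
  tr <- simulate_track(sc, seed = 1)
  st <- detect_stopovers(tr,
    pass_20e = min(tr$date), pass_50s = max(tr$date)
  )
  expect_equal(nrow(st), 1)
  expect_lte(abs(st$duration_days - 12), 1)
  expect_lt(abs(st$mean_rate - 0.3), 0.05)
})

test_that("constant fast eastward travel contains no stopovers", {
  wp <- tibble::tibble(
    date = as.Date(c("2008-09-06", "2008-10-26")),
    lat = c(-38, -42), lon = c(25, 25 + 50 * 2.5)
  )
  tr <- quick_track(wp, noise = 0)
  st <- detect_stopovers(tr, pass_20e = min(tr$date), pass_50s = max(tr$date))
  expect_equal(nrow(st), 0)
})

test_that("two plateaus separated by fast travel are two stopovers (run segmentation)", {
  d0 <- as.Date("2008-09-01")
  wp <- tibble::tibble(
    date = c(d0, d0 + 10, d0 + 30, d0 + 40, d0 + 50),
    lat = c(-38, -38, -38, -38, -38),
    lon = c(25, 25 + 10 * 0.4, 25 + 4 + 20 * 2.5, 25 + 54 + 10 * 0.4, 25 + 58 + 25)
  )
  tr <- quick_track(wp, noise = 0)
  st <- detect_stopovers(tr, pass_20e = min(tr$date), pass_50s = max(tr$date))
  expect_equal(nrow(st), 2)
  expect_gt(st$start[2] - st$end[1], 10)
})

test_that("lowering the rate criterion never increases total stopover days", {
  sc <- mean_schedule_scenario()
  tr <- simulate_track(sc, seed = 3)
  ev <- detect_events(tr)
  total_days <- function(rate) {
    st <- detect_stopovers(tr, ev$pass_20e, ev$pass_50s, rate_max = rate)
    sum(st$duration_days)
  }
  d <- vapply(c(0.3, 0.6, 1.0, 1.5), total_days, numeric(1))
  expect_true(all(diff(d) >= 0))
  # stopovers lie within the detection window
  st <- detect_stopovers(tr, ev$pass_20e, ev$pass_50s)
  expect_true(all(st$start >= ev$pass_20e & st$end <= ev$pass_50s))
})

test_that("stopovers without a detection window are an empty table", {
  sc <- mean_schedule_scenario()
  tr <- simulate_track(sc, seed = 3)
  st <- detect_stopovers(tr, pass_20e = as.Date(NA), pass_50s = as.Date("2008-11-01"))
  expect_equal(nrow(st), 0)
})

test_that("Convergence crossing classifies eastward, direct and westward patterns", {
  # built-in 27-degree eastward loop (noiseless mean schedule)
  sc <- mean_schedule_scenario(noise = 0)
  tr <- simulate_track(sc, seed = 1)
  cc <- convergence_displacement(tr, as.Date("2008-11-01"))
  expect_equal(cc$class, "eastward")
  expect_lt(abs(cc$displacement_deg - 27), 1)
  expect_equal(cc$distance_km, 27 * 60 * 1.852 * cos(50 * pi / 180),
    tolerance = 0.05
  )

  # monotone due-south crossing: direct
  wp <- tibble::tibble(
    date = as.Date(c("2008-10-20", "2008-11-12")),
    lat = c(-40, -63), lon = c(80, 80)
  )
  tr2 <- quick_track(wp, noise = 0)
  cc2 <- convergence_displacement(tr2, as.Date("2008-11-01"))
  expect_equal(cc2$class, "direct")

  # built-in 15-degree westward loop
  d0 <- as.Date("2008-10-18")
  wp3 <- tibble::tibble(
    date = c(d0, d0 + 7, d0 + 14, d0 + 21),
    lat = c(-42, -48, -55, -60),
    lon = c(60, 58, 45, 47)
  )
  tr3 <- quick_track(wp3, noise = 0)
  cc3 <- convergence_displacement(tr3, d0 + 10)
  expect_equal(cc3$class, "westward")
  expect_lt(cc3$displacement_deg, -2)
})

test_that("monthly ranges cover the residency and follow a westward drift", {
  sc <- mean_schedule_scenario(noise = 0)
  tr <- simulate_track(sc, seed = 1)
  ev <- detect_events(tr)
  mr <- monthly_ranges(tr, ev$pass_50s, ev$departure_antarctica)
  expect_setequal(mr$month, c(11, 12, 1, 2, 3))
  expect_true(all(mr$lon_min <= mr$lon_max))
  # westward drift: monthly means strictly decreasing Nov -> Mar
  expect_true(all(diff(mr$lon_mean) < 0))
  # single constant-longitude month: min equals max
  wp <- tibble::tibble(
    date = as.Date(c("2008-12-01", "2008-12-31")),
    lat = c(-65, -65), lon = c(80, 80)
  )
  trc <- quick_track(wp, noise = 0)
  mrc <- monthly_ranges(trc, as.Date("2008-12-01"), as.Date("2008-12-31"))
  expect_equal(mrc$lon_min, mrc$lon_max)
})
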