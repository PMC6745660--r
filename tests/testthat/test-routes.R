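test_that("loxodrome distance reproduces the schematic single-leg values", {
  r10 <- function(x) round(x / 10) * 10
  expect_equal(r10(loxodrome_distance(56, 14.5, 43, -31)), 3560)
  expect_equal(r10(loxodrome_distance(0, 5, -36, 20)), 4290)
  expect_equal(r10(loxodrome_distance(-65, 141, -65, -27)), 7890)
  expect_equal(loxodrome_distance(10, 20, 10, 20), 0)
  expect_error(loxodrome_distance(90, 0, 43, -31), "poles")
})

test_that("loxodrome distance is symmetric and dominates the direct chord on chains", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(2, -70, 70)
    q <- runif(2, -180, 180)
    d1 <- loxodrome_distance(p[1], q[1], p[2], q[2])
    d2 <- loxodrome_distance(p[2], q[2], p[1], q[1])
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  # any rhumb chain is at least as long as the great-circle between endpoints
  gc_km <- function(a, b) {
    d2r <- pi / 180
    ang <- acos(pmin(1, pmax(
      -1,
      sin(a[1] * d2r) * sin(b[1] * d2r) +
        cos(a[1] * d2r) * cos(b[1] * d2r) * cos((a[2] - b[2]) * d2r)
    )))
    ang / d2r * 111.12
  }
  set.seed(2)
  for (i in 1:20) {
    a <- c(runif(1, -70, 70), runif(1, -170, 170))
    b <- c(runif(1, -70, 70), runif(1, -170, 170))
    v <- (a + b) / 2 + c(runif(1, -10, 10), runif(1, -10, 10))
    via <- loxodrome_distance(a[1], a[2], v[1], v[2]) +
      loxodrome_distance(v[1], v[2], b[1], b[2])
    expect_gte(via, gc_km(a, b) - 1e-6)
  }
})

test_that("loxodrome distance agrees with an independent geodesic library to ~1 percent", {
  skip_if_not_installed("geosphere")
  set.seed(3)
  for (i in 1:10) {
    a <- c(runif(1, -70, 70), runif(1, -170, 170))
    b <- c(runif(1, -70, 70), runif(1, -170, 170))
    ours <- loxodrome_distance(a[1], a[2], b[1], b[2])
    ref <- geosphere::distRhumb(c(a[2], a[1]), c(b[2], b[1]), r = 6371008) / 1000
    expect_equal(ours, ref, tolerance = 0.011)
  }
})

test_that("chain distance sums legs and derives speed; one-leg chain is consistent", {
  spec <- segment_spec(
    "N Atlantic - Equator",
    tibble::tibble(lat = c(43, 0, 0), lon = c(-31, -13, 5)),
    "2008-07-29", "2008-08-12"
  )
  res <- chain_distance(spec)
  expect_equal(round(res$distance_km / 10) * 10, 7110)
  expect_equal(res$duration_days, 14)
  expect_equal(round(res$speed_km_day), 508)

  one <- segment_spec(
    "one-leg", tibble::tibble(lat = c(56, 43), lon = c(14.5, -31)),
    "2008-07-15", "2008-07-29"
  )
  expect_equal(
    chain_distance(one)$distance_km,
    loxodrome_distance(56, 14.5, 43, -31)
  )
  zero_dur <- segment_spec(
    "bad", tibble::tibble(lat = c(0, 1), lon = c(0, 1)),
    "2008-07-15", "2008-07-15"
  )
  expect_error(chain_distance(zero_dur), "duration")
})

test_that("the full circuit reproduces the schematic distance table", {
  tab <- circuit_table(report = TRUE)
  expect_equal(
    tab$distance_km[1:6],
    c(3560, 7110, 4290, 10880, 7890, 12710)
  )
  expect_equal(tab$distance_km[8], 50900)
  expect_equal(tab$speed_km_day[8], 179)
  expect_equal(tab$duration_days[8], 285)
  # min/max Antarctic variants bracket the mean
  min_tab <- circuit_table(tern_circuit_segments("min"), report = TRUE)
  max_tab <- circuit_table(tern_circuit_segments("max"), report = TRUE)
  ant <- function(t) t$distance_km[grep("Antarctica, E to W", t$name)]
  expect_lt(ant(min_tab), tab$distance_km[5])
  expect_gt(ant(max_tab), tab$distance_km[5])
  expect_equal(ant(min_tab), 5450)
  expect_equal(ant(max_tab), 10990)
})

test_that("parallel distance implements the 60-nautical-mile formula exactly", {
  expect_equal(parallel_distance(27, -50), 27 * 111.12 * cos(50 * pi / 180))
  expect_equal(round(parallel_distance(27, -50)), 1929) # "about 2,000 km"
  expect_equal(round(parallel_distance(116, -65) / 10) * 10, 5450)
  expect_equal(parallel_distance(0, 37), 0)
  expect_equal(parallel_distance(10, 0), 10 * 111.12)
  # linear in delta_lon
  expect_equal(parallel_distance(20, -50), 2 * parallel_distance(10, -50))
})

test_that("date statistics reproduce the reported means and spreads", {
  ev <- baltic_journey_events()
  dep <- date_stats(ev$departure_breeding)
  expect_equal(dep$sd_days, 7.1)
  expect_equal(dep$n, 11)
  expect_equal(dep$n_excluded, 1) # "beg June"
  expect_equal(format(dep$mean_date, "%d %b"), "15 Jul")

  s50 <- date_stats(ev$pass_50s)
  expect_equal(s50$sd_days, 4.8)
  expect_equal(s50$n, 11)

  expect_equal(date_stats(rep("3 May", 5))$sd_days, 0)
  expect_error(date_stats(c("beg June", "Mid-March")), "parseable")
})
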