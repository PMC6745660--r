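# Scenario builders shared across tests.

# Eastward passage with a planted slow plateau: travel at `fast` deg/day,
# plateau at `slow` deg/day for `plateau_days`, then travel again, with a
# 50S crossing at the end so the stopover window is defined.
plateau_scenario <- function(fast = 2.5, slow = 0.3, plateau_days = 12,
                             noise = 0) {
  d0 <- as.Date("2008-09-01")
  lon0 <- 25
  lon1 <- lon0 + 20 * fast # 20 fast days
  lon2 <- lon1 + plateau_days * slow
  lon3 <- lon2 + 15 * fast
  wp <- tibble::tibble(
    date = c(
      d0, d0 + 20, d0 + 20 + plateau_days, d0 + 35 + plateau_days,
      d0 + 45 + plateau_days
    ),
    lat = c(-38, -38, -38, -40, -55),
    lon = c(lon0, lon1, lon2, lon3, lon3 + 10 * fast)
  )
  trajectory_scenario(wp,
    colony = c(56, 14.5), noise = noise,
    label = "plateau"
  )
}

# track straight from a waypoint tibble, bypassing event structure
quick_track <- function(wp, colony = c(56, 14.5), noise = 0, seed = 1,
                        label = "test") {
  sc <- trajectory_scenario(wp, colony = colony, noise = noise, label = label)
  simulate_track(sc, seed = seed)
}
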