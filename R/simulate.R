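#' Simulate a geolocator light series along a track
#'
#' For every sampling instant the sun's elevation is computed at the
#' (time-interpolated) track position and pushed through the logger transfer
#' function; optional shading attenuates individual samples and Gaussian sensor
#' noise is added before clipping to `[0, clip_max]`. A track that stays poleward
#' of the polar circle in local summer yields a series that never falls below
#' the standard twilight threshold, exactly the failure mode the elevated
#' threshold ladder exists for.
#'
#' @param track tibble with columns `time` (`POSIXct` UTC), `lat`, `lon`
#'   (unwrapped degrees), e.g. from [interpolate_trajectory()]; must span at
#'   least one full day.
#' @param model a [light_model()].
#' @param seed integer seed; identical seeds give identical output.
#' @return A tibble with columns `timestamp` (`POSIXct` UTC) and `light`
#'   (instrument units), one row per sampling interval.
#' @export
simulate_light <- function(track, model = light_model(), seed = 1L) {
  if (is.null(track) || nrow(track) == 0) stop("empty track", call. = FALSE)
  stopifnot(inherits(model, "light_model"))
  span <- as.numeric(difftime(max(track$time), min(track$time), units = "hours"))
  if (span < 24) stop("track must cover at least one full day", call. = FALSE)
  ts <- seq(min(track$time), max(track$time), by = model$interval_min * 60)
  tt <- as.numeric(track$time)
  lat <- stats::approx(tt, track$lat, xout = as.numeric(ts))$y
  lon <- stats::approx(tt, track$lon, xout = as.numeric(ts))$y
  elev <- solar_elevation(ts, lat, lon)
  light <- light_transfer(model, elev)
  set.seed(seed)
  if (model$shading_prob > 0) {
    shaded <- stats::runif(length(light)) < model$shading_prob
    light[shaded] <- light[shaded] * model$shading_factor
  }
  if (model$noise_sd > 0) {
    light <- light + stats::rnorm(length(light), 0, model$noise_sd)
  }
  light <- pmin(model$clip_max, pmax(0, light))
  tibble::tibble(timestamp = ts, light = light)
}

#' Stationary track helper
#'
#' Convenience wrapper producing a fixed-position track, the setting used for
#' calibration data and for accuracy benchmarks of the threshold method.
#'
#' @param lat,lon fixed position in degrees.
#' @param start start date (`Date` or string).
#' @param days number of days.
#' @param step_hours track time step (the light sampler interpolates anyway).
#' @return A tibble with columns `time`, `lat`, `lon`.
#' @export
stationary_track <- function(lat, lon, start, days, step_hours = 6) {
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")
  times <- seq(t0, t0 + days * 86400, by = step_hours * 3600)
  tibble::tibble(time = times, lat = lat, lon = lon)
}

#' Simulate a daily geolocation track directly from a scenario
#'
#' A fast stand-in for the full light-simulation + threshold-geolocation chain:
#' samples the scenario at local noon of each day, adds position jitter, and
#' applies the validity structure that threshold geolocation would produce --
#' latitudes are dropped inside the equinox mask (|solar declination| below
#' `decl_mask` degrees) and are flagged biased (shifted equatorward, here
#' northward) during the austral-summer polar-day period, when only elevated
#' light thresholds yield twilights. Useful for testing event detection at
#' scale; the full chain is exercised by [run_pipeline()].
#'
#' @param scenario a [trajectory_scenario()].
#' @param seed integer seed.
#' @param decl_mask equinox mask half-width in degrees of declination.
#' @param polar_lat latitude south of which austral-summer latitudes are
#'   treated as polar-day biased.
#' @param polar_bias equatorward latitude bias (degrees) applied on biased days.
#' @return A track tibble (class `tern_track`): `date`, `lon`, `lat`,
#'   `lat_valid`, `lat_biased`, `n_sources`, with `colony` and `label`
#'   attributes.
#' @export
simulate_track <- function(scenario, seed = 1L, decl_mask = 7,
                           polar_lat = -55, polar_bias = 6) {
  traj <- interpolate_trajectory(scenario, step_hours = 24, seed = seed)
  dates <- as.Date(traj$time)
  decl <- solar_state(traj$time + 12 * 3600)$declination
  biased <- traj$lat < polar_lat
  masked <- abs(decl) < decl_mask & !biased
  lat <- traj$lat
  set.seed(seed + 1L)
  lat[biased] <- lat[biased] + polar_bias + stats::rnorm(sum(biased), 0, 2)
  lat[masked] <- NA_real_
  new_track(
    tibble::tibble(
      date = dates, lon = traj$lon, lat = lat,
      lat_valid = !masked & !biased & !is.na(lat),
      lat_biased = biased, n_sources = 2L
    ),
    colony = scenario$colony, label = scenario$label
  )
}
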