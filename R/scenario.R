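#' Migration trajectory scenario
#'
#' A scenario is the ground truth that the synthetic-data module samples from:
#' an ordered chain of dated waypoints joined by constant-bearing (loxodrome)
#' or great-circle interpolation, an optional list of stationary periods during
#' which longitude drifts at a fixed rate, and a position-jitter SD emulating
#' geolocation scatter. Longitudes are *unwrapped*: continuous along the
#' journey, so an eastward passage through the date line runs 170, 180, 190
#' (190E = 170W) rather than jumping to -170.
#'
#' @param waypoints data frame with columns `date` (`Date`, strictly
#'   increasing), `lat` (degrees, within \[-90, 90\]) and `lon` (unwrapped
#'   degrees; consecutive waypoints must differ by < 180 degrees).
#' @param colony length-2 numeric `c(lat, lon)` of the breeding site.
#' @param stationary_periods optional data frame with columns `start`, `end`
#'   (`Date`) and `rate` (degrees of longitude per day, east positive): within
#'   each period the track holds the latitude it had at `start` and drifts in
#'   longitude at `rate`.
#' @param noise position jitter SD in degrees (applied independently to lat
#'   and lon at each interpolated step when a seed is given).
#' @param label text identifier.
#' @param interpolation `"loxodrome"` (default, matching the route-distance
#'   convention) or `"greatcircle"`.
#' @return An object of class `trajectory_scenario`.
#' @seealso [mean_schedule_scenario()], [interpolate_trajectory()]
#' @export
trajectory_scenario <- function(waypoints, colony, stationary_periods = NULL,
                                noise = 0, label = "scenario",
                                interpolation = c("loxodrome", "greatcircle")) {
  interpolation <- match.arg(interpolation)
  waypoints <- tibble::as_tibble(waypoints)
  stopifnot(all(c("date", "lat", "lon") %in% names(waypoints)))
  waypoints$date <- as.Date(waypoints$date)
  if (nrow(waypoints) < 2) stop("need at least two waypoints", call. = FALSE)
  if (any(diff(as.numeric(waypoints$date)) <= 0)) {
    stop("waypoint dates must be strictly increasing", call. = FALSE)
  }
  if (any(abs(waypoints$lat) > 90)) {
    stop("waypoint latitudes must lie in [-90, 90]", call. = FALSE)
  }
  if (any(abs(diff(waypoints$lon)) >= 180)) {
    stop(
      "waypoint longitudes must be unwrapped (consecutive difference < 180)",
      call. = FALSE
    )
  }
  stopifnot(length(colony) == 2, abs(colony[1]) <= 90)
  if (!is.null(stationary_periods)) {
    stationary_periods <- tibble::as_tibble(stationary_periods)
    stopifnot(all(c("start", "end", "rate") %in% names(stationary_periods)))
    stationary_periods$start <- as.Date(stationary_periods$start)
    stationary_periods$end <- as.Date(stationary_periods$end)
    if (any(stationary_periods$end < stationary_periods$start)) {
      stop("stationary periods must have end >= start", call. = FALSE)
    }
  }
  if (noise < 0) stop("`noise` must be non-negative", call. = FALSE)
  structure(
    list(
      waypoints = waypoints, colony = c(lat = unname(colony[1]), lon = unname(colony[2])),
      stationary_periods = stationary_periods, noise = noise, label = label,
      interpolation = interpolation
    ),
    class = "trajectory_scenario"
  )
}

#' @export
print.trajectory_scenario <- function(x, ...) {
  cat(sprintf(
    "<trajectory_scenario '%s'> %d waypoints, %s to %s, %s interpolation, jitter sd %.2f deg\n",
    x$label, nrow(x$waypoints), format(min(x$waypoints$date)),
    format(max(x$waypoints$date)), x$interpolation, x$noise
  ))
  invisible(x)
}

# Mercator latitude in degrees
mercator_lat <- function(lat) 180 / pi * log(tan(pi / 4 + lat * pi / 360))
inv_mercator_lat <- function(psi) 360 / pi * atan(exp(psi * pi / 180)) - 90

# interpolate one leg at fractions f in [0, 1]
interp_leg <- function(lat1, lon1, lat2, lon2, f, method) {
  if (method == "loxodrome") {
    # straight line in (Mercator latitude, longitude): constant bearing
    psi <- mercator_lat(lat1) + f * (mercator_lat(lat2) - mercator_lat(lat1))
    lat <- if (abs(lat2 - lat1) < 1e-12) rep(lat1, length(f)) else inv_mercator_lat(psi)
    lon <- lon1 + f * (lon2 - lon1)
  } else {
    # spherical linear interpolation on the unit sphere
    d2r <- pi / 180
    p1 <- c(cos(lat1 * d2r) * cos(lon1 * d2r), cos(lat1 * d2r) * sin(lon1 * d2r), sin(lat1 * d2r))
    p2 <- c(cos(lat2 * d2r) * cos(lon2 * d2r), cos(lat2 * d2r) * sin(lon2 * d2r), sin(lat2 * d2r))
    ang <- acos(min(1, max(-1, sum(p1 * p2))))
    if (ang < 1e-12) {
      lat <- rep(lat1, length(f))
      lon <- rep(lon1, length(f))
    } else {
      w1 <- sin((1 - f) * ang) / sin(ang)
      w2 <- sin(f * ang) / sin(ang)
      px <- w1 * p1[1] + w2 * p2[1]
      py <- w1 * p1[2] + w2 * p2[2]
      pz <- w1 * p1[3] + w2 * p2[3]
      lat <- asin(pz / sqrt(px^2 + py^2 + pz^2)) / d2r
      lon <- atan2(py, px) / d2r
      # re-anchor on the unwrapped line of the leg
      lon <- lon + 360 * round((lon1 + f * (lon2 - lon1) - lon) / 360)
    }
  }
  list(lat = lat, lon = lon)
}

#' Interpolate a scenario into a time-indexed track
#'
#' Positions at every `step_hours` between the first and last waypoint date
#' (waypoints are anchored at 00:00 UTC). Within stationary periods the
#' latitude is held and longitude drifts at the period's rate. With `seed`
#' given and `scenario$noise > 0`, independent Gaussian jitter is added to
#' latitude and longitude at each step.
#'
#' @param scenario a [trajectory_scenario()].
#' @param step_hours time step in hours; must not exceed the shortest waypoint
#'   gap.
#' @param seed optional integer seed for the jitter (no jitter if `NULL` or
#'   `scenario$noise == 0`).
#' @return A tibble with columns `time` (`POSIXct` UTC), `lat`, `lon`
#'   (unwrapped degrees).
#' @export
interpolate_trajectory <- function(scenario, step_hours = 24, seed = NULL) {
  stopifnot(inherits(scenario, "trajectory_scenario"))
  wp <- scenario$waypoints
  gaps <- diff(as.numeric(wp$date)) * 24
  if (step_hours > min(gaps)) {
    stop(sprintf(
      "step (%g h) exceeds the shortest waypoint gap (%g h)",
      step_hours, min(gaps)
    ), call. = FALSE)
  }
  t0 <- as.POSIXct(paste(wp$date[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(wp$date[nrow(wp)], "00:00:00"), tz = "UTC")
  times <- seq(t0, t1, by = step_hours * 3600)
  wp_t <- as.numeric(as.POSIXct(paste(wp$date, "00:00:00"), tz = "UTC"))
  leg <- findInterval(as.numeric(times), wp_t, rightmost.closed = TRUE)
  lat <- numeric(length(times))
  lon <- numeric(length(times))
  for (i in unique(leg)) {
    sel <- leg == i
    f <- (as.numeric(times[sel]) - wp_t[i]) / (wp_t[i + 1] - wp_t[i])
    pos <- interp_leg(
      wp$lat[i], wp$lon[i], wp$lat[i + 1], wp$lon[i + 1],
      f, scenario$interpolation
    )
    lat[sel] <- pos$lat
    lon[sel] <- pos$lon
  }
  if (!is.null(scenario$stationary_periods)) {
    sp <- scenario$stationary_periods
    for (j in seq_len(nrow(sp))) {
      s0 <- as.POSIXct(paste(sp$start[j], "00:00:00"), tz = "UTC")
      s1 <- as.POSIXct(paste(sp$end[j], "00:00:00"), tz = "UTC")
      sel <- times >= s0 & times <= s1
      if (!any(sel)) next
      at0 <- which(sel)[1]
      lat[sel] <- lat[at0]
      lon[sel] <- lon[at0] + sp$rate[j] *
        as.numeric(difftime(times[sel], times[at0], units = "days"))
    }
  }
  if (!is.null(seed) && scenario$noise > 0) {
    set.seed(seed)
    lat <- pmin(90, pmax(-90, lat + stats::rnorm(length(lat), 0, scenario$noise)))
    lon <- lon + stats::rnorm(length(lon), 0, scenario$noise)
  }
  tibble::tibble(time = times, lat = lat, lon = lon)
}

#' Read a trajectory scenario from a YAML file
#'
#' Expected structure: top-level keys `label`, `colony` (`[lat, lon]`),
#' `noise`, `interpolation`, `waypoints` (list of `{date, lat, lon}` with
#' ISO-8601 dates) and optionally `stationary_periods` (list of
#' `{start, end, rate}`).
#'
#' @param path file path.
#' @return A [trajectory_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  wp <- dplyr::bind_rows(lapply(y$waypoints, tibble::as_tibble))
  sp <- if (!is.null(y$stationary_periods)) {
    dplyr::bind_rows(lapply(y$stationary_periods, tibble::as_tibble))
  }
  trajectory_scenario(
    waypoints = wp,
    colony = unlist(y$colony),
    stationary_periods = sp,
    noise = y$noise %||% 0,
    label = y$label %||% "scenario",
    interpolation = y$interpolation %||% "loxodrome"
  )
}

#' Write a trajectory scenario to a YAML file
#'
#' @param scenario a [trajectory_scenario()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  y <- list(
    label = scenario$label,
    colony = as.numeric(scenario$colony),
    noise = scenario$noise,
    interpolation = scenario$interpolation,
    waypoints = lapply(seq_len(nrow(scenario$waypoints)), function(i) {
      list(
        date = format(scenario$waypoints$date[i]),
        lat = scenario$waypoints$lat[i],
        lon = scenario$waypoints$lon[i]
      )
    })
  )
  if (!is.null(scenario$stationary_periods)) {
    y$stationary_periods <- lapply(
      seq_len(nrow(scenario$stationary_periods)),
      function(i) {
        list(
          start = format(scenario$stationary_periods$start[i]),
          end = format(scenario$stationary_periods$end[i]),
          rate = scenario$stationary_periods$rate[i]
        )
      }
    )
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Mean-schedule Baltic tern scenario
#'
#' A built-in scenario encoding the mean annual schedule of the tracked Baltic
#' journeys: residence at the colony (56N, 14.5E) from 1 July (providing a
#' clean calibration window), departure on 15 July, the North
#' Atlantic longitude dip to 43N/31W on 29 July, equator crossing 12 August,
#' passage of 20E into the Indian Ocean on 6 September, a slow-movement
#' (stopover) plateau near 60-68E in late September/early October, crossing of
#' 50S on 1 November with a built-in 27-degree eastward displacement, furthest
#' east 141E on 7 November, westward drift through the Antarctic zone reaching
#' 71E on 1 January and the Weddell Sea (27W) on 13 March, a fast northeastward
#' spring exit, the spring North Atlantic dip at 34N/34W on 10 April, and
#' arrival back at the colony on 26 April followed by renewed residence there.
#'
#' The true event dates and positions implied by the waypoints are attached as
#' `attr(x, "truth")`, so recovery of events from simulated data can be scored
#' against ground truth.
#'
#' @param noise position jitter SD in degrees (default 0.5, a typical
#'   geolocator longitude scatter).
#' @param start_year year of the July departure.
#' @return A [trajectory_scenario()] with a `truth` attribute.
#' @export
mean_schedule_scenario <- function(noise = 0.5, start_year = 2008) {
  y0 <- start_year
  y1 <- start_year + 1
  d <- function(y, md) as.Date(sprintf("%d-%s", y, md))
  wp <- tibble::tibble(
    date = c(
      d(y0, "07-01"), d(y0, "07-15"), d(y0, "07-29"), d(y0, "08-12"),
      d(y0, "08-25"), d(y0, "09-06"), d(y0, "09-25"), d(y0, "10-10"),
      d(y0, "10-25"), d(y0, "11-01"), d(y0, "11-07"), d(y1, "01-01"),
      d(y1, "03-13"), d(y1, "03-21"), d(y1, "04-10"), d(y1, "04-26"),
      d(y1, "05-06")
    ),
    lat = c(
      56, 56, 43, 0, -30, -37, -38, -38, -45, -50, -63, -65, -65, -48,
      34, 56, 56
    ),
    lon = c(
      14.5, 14.5, -31, -13, 12, 20, 60, 68, 114, 128, 141, 71, -27, 3,
      -34, 14.5, 14.5
    )
  )
  sc <- trajectory_scenario(
    waypoints = wp, colony = c(56, 14.5), noise = noise,
    label = "baltic-mean-schedule"
  )
  truth <- tibble::tibble(
    event = c(
      "departure_breeding", "natl_furthest_w", "equator_crossing", "pass_20e",
      "pass_50s", "furthest_e", "antarctic_furthest_w", "departure_antarctica",
      "natl_furthest_w_spring", "arrival_breeding"
    ),
    date = c(
      d(y0, "07-15"), d(y0, "07-29"), d(y0, "08-12"), d(y0, "09-06"),
      d(y0, "11-01"), d(y0, "11-07"), d(y1, "03-13"), d(y1, "03-13"),
      d(y1, "04-10"), d(y1, "04-26")
    ),
    lon = c(14.5, -31, -13, 20, 128, 141, -27, -27, -34, 14.5),
    lat = c(56, 43, 0, -37, -50, -63, -65, -65, 34, 56)
  )
  attr(sc, "truth") <- truth
  sc
}
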