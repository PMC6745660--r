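KM_PER_DEG <- 60 * 1.852 # 1 degree of latitude = 60 nautical miles = 111.12 km

#' Rhumb-line (loxodrome) distance between two points
#'
#' Distance along the constant-bearing path, on a sphere scaled so that one
#' degree of latitude is 60 nautical miles (111.12 km) -- the schematic
#' convention used for migration-circuit distances. The bearing comes from the
#' Mercator latitude \eqn{\psi = \ln\tan(45^\circ + \phi/2)}:
#' \eqn{\theta = \mathrm{atan2}(\Delta\lambda, \Delta\psi)}, and the distance is
#' \eqn{|\Delta\phi| \cdot 111.12 / |\cos\theta|}; a pure east-west leg reduces
#' to \eqn{|\Delta\lambda| \cdot 111.12 \cos\phi}. Longitudes are taken as
#' unwrapped: a leg from 141E to -27 (27W) runs westward across 168 degrees,
#' not eastward across 192.
#'
#' @param lat1,lon1,lat2,lon2 endpoints in degrees; latitudes strictly inside
#'   (-90, 90).
#' @return Distance in km (unrounded).
#' @examples
#' loxodrome_distance(56, 14.5, 43, -31) # breeding area to N Atlantic dip
#' @export
loxodrome_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) >= 90)) {
    stop("loxodrome distance is undefined at the poles", call. = FALSE)
  }
  dphi <- lat2 - lat1
  dlam <- lon2 - lon1
  if (abs(dphi) < 1e-12) {
    return(abs(dlam) * KM_PER_DEG * cos(lat1 * pi / 180))
  }
  dpsi <- mercator_lat(lat2) - mercator_lat(lat1)
  theta <- atan2(dlam, dpsi)
  abs(dphi) * KM_PER_DEG / abs(cos(theta))
}

#' Segment specification: a dated waypoint chain
#'
#' @param name segment name.
#' @param waypoints data frame with columns `lat`, `lon` (unwrapped degrees),
#'   at least two rows.
#' @param start,end segment dates (`Date` or string).
#' @return A list of class `segment_spec`.
#' @export
segment_spec <- function(name, waypoints, start, end) {
  waypoints <- tibble::as_tibble(waypoints)
  stopifnot(all(c("lat", "lon") %in% names(waypoints)), nrow(waypoints) >= 2)
  # longitudes are interpreted as unwrapped: a leg from 207 to -27 runs 234
  # degrees westward, it is not reduced modulo 360
  structure(
    list(
      name = name, waypoints = waypoints,
      start = as.Date(start), end = as.Date(end)
    ),
    class = "segment_spec"
  )
}

#' Distance, duration and speed of a waypoint chain
#'
#' Sums the rhumb-line legs of the chain and derives the duration from the
#' segment dates and the speed as distance/duration. By default legs are summed
#' unrounded and any rounding is left to report time; `round_legs = TRUE`
#' instead rounds each leg to the nearest 10 km before summing, the convention
#' under which a hand-assembled distance table (one rounded number per leg) is
#' reproduced exactly.
#'
#' @param spec a [segment_spec()].
#' @param round_legs round each leg to the nearest 10 km before summing.
#' @return A one-row tibble: `name`, `start`, `end`, `duration_days`,
#'   `distance_km`, `speed_km_day`.
#' @export
chain_distance <- function(spec, round_legs = FALSE) {
  stopifnot(inherits(spec, "segment_spec"))
  wp <- spec$waypoints
  legs <- vapply(seq_len(nrow(wp) - 1), function(i) {
    loxodrome_distance(wp$lat[i], wp$lon[i], wp$lat[i + 1], wp$lon[i + 1])
  }, numeric(1))
  if (round_legs) legs <- round(legs / 10) * 10
  dist <- sum(legs)
  dur <- as.numeric(spec$end - spec$start)
  if (dur <= 0) stop("segment duration must be positive", call. = FALSE)
  tibble::tibble(
    name = spec$name, start = spec$start, end = spec$end,
    duration_days = dur, distance_km = dist, speed_km_day = dist / dur
  )
}

#' Distance along a parallel of latitude
#'
#' The schematic along-parallel displacement distance:
#' `delta_lon x 60 nautical miles x cos(lat)`.
#'
#' @param delta_lon longitude difference in degrees.
#' @param lat latitude of the parallel in degrees, strictly inside (-90, 90).
#' @return Distance in km.
#' @examples
#' parallel_distance(27, -50) # mean Convergence-crossing displacement
#' @export
parallel_distance <- function(delta_lon, lat) {
  stopifnot(abs(lat) < 90)
  delta_lon * KM_PER_DEG * cos(lat * pi / 180)
}

#' Round a segment-result table for reporting
#'
#' Distances to the nearest 10 km, speeds to the nearest 1 km/day.
#'
#' @param segments tibble from [chain_distance()] rows.
#' @return The tibble with `distance_km` and `speed_km_day` rounded.
#' @export
round_segments <- function(segments) {
  dplyr::mutate(segments,
    distance_km = round(.data$distance_km / 10) * 10,
    speed_km_day = round(.data$speed_km_day)
  )
}

#' Mean date and spread of a set of calendar dates
#'
#' Computes the mean and the (n-1)-denominator standard deviation, in days, of
#' a vector of dates given as day-month strings (e.g. `"15 July"`, `"c. 29
#' October"`). Entries that do not parse to a specific day (e.g. `"beg June"`,
#' `"Mid-March"`) are excluded and counted. Day-of-year arithmetic uses a fixed
#' non-leap reference year, so mixed-year inputs differ by at most one day from
#' exact-calendar arithmetic.
#'
#' @param dates character vector of day-month dates, or a `Date` vector.
#' @return A list: `mean_date` (`Date` in the reference year), `mean_label`
#'   (`"15 July"` style), `sd_days` (1 decimal), `n`, `n_excluded`.
#' @export
date_stats <- function(dates) {
  ref_year <- 2001 # non-leap
  if (inherits(dates, "Date")) {
    doy <- as.numeric(format(dates, "%j"))
    n_excl <- 0L
  } else {
    cleaned <- sub("^c\\.\\s*", "", trimws(dates))
    parsed <- as.Date(paste(cleaned, ref_year), format = "%d %B %Y")
    n_excl <- sum(is.na(parsed))
    doy <- as.numeric(format(parsed[!is.na(parsed)], "%j"))
  }
  if (length(doy) < 2) {
    stop("need at least two parseable dates", call. = FALSE)
  }
  mean_date <- as.Date(round(mean(doy)) - 1, origin = sprintf("%d-01-01", ref_year))
  list(
    mean_date = mean_date,
    mean_label = format(mean_date, "%e %B") |> trimws(),
    sd_days = round(stats::sd(doy), 1),
    n = length(doy),
    n_excluded = n_excl
  )
}
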