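#' Event-detection configuration
#'
#' Formal thresholds for deriving annual-cycle events from a daily longitude
#' (and, where valid, latitude) track. The source data for such events are
#' dominated by longitude, which stays reliable through the equinoxes and the
#' polar day, so most definitions are longitude-trend rules.
#'
#' @param departure_lon_offset degrees west of the colony longitude that a
#'   sustained westward trend must reach to count as departure.
#' @param trend_days minimum sustained-trend length in days.
#' @param smooth_days window of the rolling-median smoother applied to
#'   longitude before trend analysis (odd integer).
#' @param natl_window_days search window after departure for the North Atlantic
#'   furthest-west dip.
#' @param exit_rate_min minimum sustained eastward rate (degrees/day) that
#'   marks the spring departure from Antarctica.
#' @param exit_months calendar months in which the Antarctic departure is
#'   searched.
#' @param arrival_lon_tol,arrival_lat_tol proximity to the colony (degrees of
#'   longitude; degrees of valid latitude) that counts as arrival.
#' @param crossing_max_gap_days maximum gap between valid-latitude days across
#'   which an equator/50S crossing is interpolated.
#' @param trend_eps minimum daily longitude step (degrees) counted as real
#'   travel rather than position scatter when tracing a trend to its onset.
#' @return A list of class `event_config`.
#' @export
event_config <- function(departure_lon_offset = 3, trend_days = 3,
                         smooth_days = 3, natl_window_days = 45,
                         exit_rate_min = 3, exit_months = 2:4,
                         arrival_lon_tol = 2, arrival_lat_tol = 3,
                         crossing_max_gap_days = 10, trend_eps = 0.3) {
  structure(
    list(
      departure_lon_offset = departure_lon_offset, trend_days = trend_days,
      smooth_days = smooth_days, natl_window_days = natl_window_days,
      exit_rate_min = exit_rate_min, exit_months = exit_months,
      arrival_lon_tol = arrival_lon_tol, arrival_lat_tol = arrival_lat_tol,
      crossing_max_gap_days = crossing_max_gap_days, trend_eps = trend_eps
    ),
    class = "event_config"
  )
}

# interpolated date at which `y` crosses `level` between consecutive valid rows
interp_crossing_date <- function(dates, y, level, downward, max_gap) {
  ok <- !is.na(y)
  d <- dates[ok]
  v <- y[ok]
  if (length(v) < 2) return(as.Date(NA))
  for (i in seq_len(length(v) - 1)) {
    gap <- as.numeric(d[i + 1] - d[i])
    if (gap > max_gap) next
    hit <- if (downward) v[i] > level && v[i + 1] <= level else
      v[i] < level && v[i + 1] >= level
    if (hit) {
      f <- (level - v[i]) / (v[i + 1] - v[i])
      return(d[i] + round(f * gap))
    }
  }
  as.Date(NA)
}

#' Detect annual-cycle migration events from a daily track
#'
#' Derives the phenology table of one journey: breeding-area departure (first
#' sustained westward longitude trend taking the track more than
#' `departure_lon_offset` degrees west of the colony), the North Atlantic
#' furthest-west dip, the (interpolated, valid-latitude) equator and 50S
#' crossings, the eastbound passage of 20E into the Indian Ocean, furthest east,
#' the Antarctic furthest west, the spring departure from Antarctica (onset of
#' a sustained fast eastward exit), the spring North Atlantic dip, and arrival
#' back at the colony. Events whose search window has no data are returned as
#' missing, mirroring real deployments that stop recording mid-journey.
#'
#' Longitudes are canonicalised first (the whole series is shifted by a
#' multiple of 360 degrees so the journey starts at the colony), so detection
#' is invariant to adding 360 to every longitude.
#'
#' @param track a `tern_track` (from [assemble_track()] or [simulate_track()]).
#' @param config an [event_config()].
#' @return A one-row tibble with columns `journey`, `departure_breeding`,
#'   `natl_furthest_w_date`, `natl_furthest_w_lon`, `natl_furthest_w_lat`,
#'   `equator_crossing`, `pass_20e`, `pass_50s`, `furthest_e_date`,
#'   `furthest_e_lon`, `antarctic_furthest_w_date`, `antarctic_furthest_w_lon`,
#'   `departure_antarctica`, `natl_furthest_w_spring_date`,
#'   `natl_furthest_w_spring_lon`, `natl_furthest_w_spring_lat`,
#'   `arrival_breeding`.
#' @export
detect_events <- function(track, config = event_config()) {
  stopifnot(inherits(track, "tern_track"))
  colony <- attr(track, "colony")
  cfg <- config
  na_row <- tibble::tibble(
    journey = attr(track, "label"),
    departure_breeding = as.Date(NA),
    natl_furthest_w_date = as.Date(NA), natl_furthest_w_lon = NA_real_,
    natl_furthest_w_lat = NA_real_,
    equator_crossing = as.Date(NA), pass_20e = as.Date(NA),
    pass_50s = as.Date(NA),
    furthest_e_date = as.Date(NA), furthest_e_lon = NA_real_,
    antarctic_furthest_w_date = as.Date(NA), antarctic_furthest_w_lon = NA_real_,
    departure_antarctica = as.Date(NA),
    natl_furthest_w_spring_date = as.Date(NA),
    natl_furthest_w_spring_lon = NA_real_, natl_furthest_w_spring_lat = NA_real_,
    arrival_breeding = as.Date(NA)
  )
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$date)
  if (nrow(tr) < cfg$smooth_days + 2) return(na_row)
  # canonicalise the unwrapped series onto the colony's 360-degree branch
  shift <- 360 * round((tr$lon[1] - colony["lon"]) / 360)
  tr$lon <- tr$lon - shift
  s <- as.numeric(stats::runmed(tr$lon, cfg$smooth_days, endrule = "median"))
  dts <- tr$date
  days <- as.numeric(dts)
  ev <- na_row

  # departure: first sustained westward run reaching colony_lon - offset;
  # walk back along daily steps larger than `trend_eps` (real travel, not
  # scatter) to the last stable colony day, and date the departure after it
  hit <- which(s <= colony["lon"] - cfg$departure_lon_offset)
  if (length(hit)) {
    i <- hit[1]
    while (i > 1 && s[i - 1] - s[i] > cfg$trend_eps) i <- i - 1
    dep_idx <- min(i + 1, length(s))
    ev$departure_breeding <- dts[dep_idx]

    # North Atlantic furthest west: minimum of the autumn dip
    win <- which(dts >= dts[dep_idx] &
      dts <= dts[dep_idx] + cfg$natl_window_days)
    if (length(win)) {
      imin <- win[which.min(s[win])]
      ev$natl_furthest_w_date <- dts[imin]
      ev$natl_furthest_w_lon <- tr$lon[imin]
      ev$natl_furthest_w_lat <- ifelse(tr$lat_valid[imin], tr$lat[imin], NA_real_)
    }

    after_dep <- dts >= dts[dep_idx]
    lat_use <- ifelse(tr$lat_valid, tr$lat, NA_real_)
    ev$equator_crossing <- interp_crossing_date(
      dts[after_dep], lat_use[after_dep], 0,
      downward = TRUE, cfg$crossing_max_gap_days
    )

    # eastbound crossing of 20E after the Atlantic dip
    if (!is.na(ev$natl_furthest_w_date)) {
      aft <- which(dts >= ev$natl_furthest_w_date)
      ev$pass_20e <- interp_crossing_date(
        dts[aft], s[aft], 20,
        downward = FALSE, cfg$crossing_max_gap_days
      )
    }

    from <- if (!is.na(ev$pass_20e)) ev$pass_20e else dts[dep_idx]
    aft <- which(dts >= from)
    ev$pass_50s <- interp_crossing_date(
      dts[aft], lat_use[aft], -50,
      downward = TRUE, cfg$crossing_max_gap_days
    )

    # furthest east of the whole journey
    post <- which(dts >= dts[dep_idx])
    imax <- post[which.max(s[post])]
    ev$furthest_e_date <- dts[imax]
    ev$furthest_e_lon <- tr$lon[imax]

    # spring departure from Antarctica: onset of fast sustained eastward exit
    k <- cfg$trend_days
    cand <- which(
      dts > dts[imax] &
        as.integer(format(dts, "%m")) %in% cfg$exit_months &
        seq_along(dts) <= length(dts) - k
    )
    dep_ant_idx <- NA_integer_
    for (i in cand) {
      dt <- days[i + k] - days[i]
      if (dt > 2 * k) next # data gap
      rate <- (s[i + k] - s[i]) / dt
      steps <- diff(s[i:(i + k)])
      if (rate > cfg$exit_rate_min && all(steps > 0)) {
        dep_ant_idx <- i
        break
      }
    }
    if (!is.na(dep_ant_idx)) {
      ev$departure_antarctica <- dts[dep_ant_idx]
      win <- which(dts > dts[imax] & dts <= dts[dep_ant_idx])
      if (length(win)) {
        iw <- win[which.min(s[win])]
        ev$antarctic_furthest_w_date <- dts[iw]
        ev$antarctic_furthest_w_lon <- tr$lon[iw]
      }
      # spring North Atlantic dip
      win2 <- which(dts > dts[dep_ant_idx] + 2)
      if (length(win2)) {
        iw2 <- win2[which.min(s[win2])]
        ev$natl_furthest_w_spring_date <- dts[iw2]
        ev$natl_furthest_w_spring_lon <- tr$lon[iw2]
        ev$natl_furthest_w_spring_lat <-
          ifelse(tr$lat_valid[iw2], tr$lat[iw2], NA_real_)
        # arrival: back within tolerance of the colony
        win3 <- which(dts >= dts[iw2] &
          abs(tr$lon - colony["lon"]) <= cfg$arrival_lon_tol &
          tr$lat_valid &
          abs(tr$lat - colony["lat"]) <= cfg$arrival_lat_tol)
        if (length(win3)) ev$arrival_breeding <- dts[win3[1]]
      }
    }
  }
  ev
}

#' Detect stopovers along the eastward Indian Ocean passage
#'
#' A stopover is a maximal run of days whose centred rolling longitude slope
#' (least-squares over a `slope_window`-day window) does not exceed `rate_max`
#' degrees per day, merged across single-day gaps, lasting at least `min_days`,
#' and lying inside the detection window: between the 20E passage and the 50S
#' crossing, east of 20E.
#'
#' @param track a `tern_track`.
#' @param pass_20e,pass_50s window bounds (`Date`); typically from
#'   [detect_events()]. With either missing, an empty table is returned.
#' @param rate_max stopover criterion in degrees of longitude per day.
#' @param min_days minimum stopover duration in days.
#' @param slope_window centred window (days) of the rolling least-squares slope.
#' @return A tibble with one row per stopover: `start`, `end`, `duration_days`,
#'   `lon_min`, `lon_max`, `mean_rate`, `mean_lat`.
#' @export
detect_stopovers <- function(track, pass_20e, pass_50s, rate_max = 1.0,
                             min_days = 5, slope_window = 5) {
  empty <- tibble::tibble(
    start = as.Date(character()), end = as.Date(character()),
    duration_days = numeric(), lon_min = numeric(), lon_max = numeric(),
    mean_rate = numeric(), mean_lat = numeric()
  )
  if (is.na(pass_20e) || is.na(pass_50s)) return(empty)
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$date)
  tr <- tr[tr$date >= as.Date(pass_20e) & tr$date <= as.Date(pass_50s) &
    tr$lon > 20, ]
  if (nrow(tr) < min_days) return(empty)
  days <- as.numeric(tr$date)
  half <- (slope_window - 1) / 2
  slope <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- which(abs(days - days[i]) <= half)
    if (length(sel) < 3) return(NA_real_)
    stats::coef(stats::lm(tr$lon[sel] ~ days[sel]))[2]
  }, numeric(1))
  cand <- which(!is.na(slope) & slope <= rate_max)
  if (!length(cand)) return(empty)
  # merge candidate runs across single-day gaps (date gap of 2 = one-day hole)
  runs <- split(cand, cumsum(c(TRUE, diff(days[cand]) > 2)))
  out <- purrr::map_dfr(runs, function(idx) {
    span <- as.numeric(tr$date[max(idx)] - tr$date[min(idx)]) + 1
    if (span < min_days) return(NULL)
    lat_ok <- tr$lat_valid[idx] & !is.na(tr$lat[idx])
    tibble::tibble(
      start = tr$date[min(idx)], end = tr$date[max(idx)],
      duration_days = span,
      lon_min = min(tr$lon[idx]), lon_max = max(tr$lon[idx]),
      mean_rate = (tr$lon[max(idx)] - tr$lon[min(idx)]) / (span - 1),
      mean_lat = if (any(lat_ok)) mean(tr$lat[idx][lat_ok]) else NA_real_
    )
  })
  if (nrow(out) == 0) empty else out
}

#' Eastward displacement across the Antarctic Convergence
#'
#' Quantifies the longitude peak that typically accompanies the southbound 50S
#' crossing: within `window_days` of the crossing, the signed displacement is
#' the larger of (max longitude - longitude at window start) and -(longitude at
#' window start - min longitude). Crossings with |displacement| below
#' `direct_tol` are classified `"direct"`, negative ones `"westward"`, the rest
#' `"eastward"`. The displacement distance uses the along-parallel formula at
#' 50S ([parallel_distance()]).
#'
#' @param track a `tern_track`.
#' @param pass_50s crossing date (from [detect_events()]).
#' @param window_days half-width of the window around the crossing.
#' @param direct_tol displacement magnitude (degrees) below which the crossing
#'   counts as direct.
#' @return A one-row tibble: `crossing_date`, `pre_lon`, `peak_lon`,
#'   `displacement_deg`, `distance_km`, `class`; or a row of `NA`s when the
#'   crossing or its window is missing.
#' @export
convergence_displacement <- function(track, pass_50s, window_days = 7,
                                     direct_tol = 2) {
  na_row <- tibble::tibble(
    crossing_date = as.Date(NA), pre_lon = NA_real_, peak_lon = NA_real_,
    displacement_deg = NA_real_, distance_km = NA_real_, class = NA_character_
  )
  if (is.na(pass_50s)) return(na_row)
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$date)
  win <- tr[tr$date >= as.Date(pass_50s) - window_days &
    tr$date <= as.Date(pass_50s) + window_days, ]
  if (nrow(win) < 3) return(na_row)
  start_lon <- win$lon[1]
  east <- max(win$lon) - start_lon
  west <- start_lon - min(win$lon)
  disp <- if (east >= west) east else -west
  cls <- if (abs(disp) < direct_tol) {
    "direct"
  } else if (disp > 0) "eastward" else "westward"
  tibble::tibble(
    crossing_date = as.Date(pass_50s),
    pre_lon = start_lon,
    peak_lon = if (disp >= 0) max(win$lon) else min(win$lon),
    displacement_deg = disp,
    distance_km = parallel_distance(abs(disp), -50),
    class = cls
  )
}

#' Monthly longitude ranges during the Antarctic residency
#'
#' Minimum, maximum and mean longitude per calendar month between the 50S
#' crossing and the Antarctic departure (residency is bounded by these two
#' longitude-derived events rather than by a latitude criterion, because
#' Antarctic-summer latitudes are biased).
#'
#' @param track a `tern_track`.
#' @param pass_50s,departure_antarctica residency bounds (`Date`);
#'   `departure_antarctica` may be `NA` (end of track used).
#' @param months calendar months to report (default November-March).
#' @return A tibble with one row per year-month: `journey`, `year`, `month`,
#'   `lon_min`, `lon_max`, `lon_mean`, `n_days`.
#' @export
monthly_ranges <- function(track, pass_50s, departure_antarctica = NA,
                           months = c(11, 12, 1, 2, 3)) {
  empty <- tibble::tibble(
    journey = character(), year = integer(), month = integer(),
    lon_min = numeric(), lon_max = numeric(), lon_mean = numeric(),
    n_days = integer()
  )
  if (is.na(pass_50s)) return(empty)
  tr <- tibble::as_tibble(track)
  hi <- if (is.na(departure_antarctica)) max(tr$date) else as.Date(departure_antarctica)
  tr <- tr[tr$date >= as.Date(pass_50s) & tr$date <= hi, ]
  tr <- tr[as.integer(format(tr$date, "%m")) %in% months, ]
  if (!nrow(tr)) return(empty)
  tr$year <- as.integer(format(tr$date, "%Y"))
  tr$month <- as.integer(format(tr$date, "%m"))
  tr |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      lon_min = min(.data$lon), lon_max = max(.data$lon),
      lon_mean = mean(.data$lon), n_days = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(journey = attr(track, "label"), .before = 1) |>
    dplyr::arrange(.data$year, .data$month)
}
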