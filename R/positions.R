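#' Longitude from the timing of local solar noon or midnight
#'
#' The midpoint of a sunrise/sunset pair is local apparent noon (for a day
#' pair) or local apparent midnight (for a night pair, sunset before sunrise).
#' Correcting apparent for mean solar time with the equation of time gives
#' longitude at 15 degrees per hour, east positive.
#'
#' @param sunrise,sunset `POSIXct` twilight instants (UTC). If `sunrise <
#'   sunset` the pair brackets a day and local noon is used; otherwise it
#'   brackets a night and local midnight is used.
#' @return Longitude in degrees within (-180, 180].
#' @export
longitude_from_noon <- function(sunrise, sunset) {
  gap_h <- abs(as.numeric(difftime(sunset, sunrise, units = "hours")))
  if (any(gap_h > 24)) stop("twilight pair spans more than 24 h", call. = FALSE)
  mid <- sunrise + as.numeric(difftime(sunset, sunrise, units = "secs")) / 2
  s <- solar_state(mid)
  lt <- as.POSIXlt(mid, tz = "UTC")
  utc_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  # apparent solar time at the logger equals 12 h (noon) or 0/24 h (midnight)
  target <- ifelse(sunrise < sunset, 12, 24)
  lam <- 15 * (target - utc_h - s$eqtime / 60)
  wrap_lon(lam)
}

# wrap to (-180, 180]
wrap_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Latitude from day length (the sunrise equation)
#'
#' Solves the sunrise equation
#' \deqn{\cos H = \frac{\sin a_0 - \sin\phi \sin\delta}{\cos\phi \cos\delta}}
#' for latitude \eqn{\phi}, where the half-day hour angle \eqn{H} is fixed by
#' the observed day length and \eqn{a_0} is the calibrated sun elevation of the
#' light threshold. Near the equinoxes day length is almost independent of
#' latitude, so the estimate is marked invalid when the local sensitivity
#' |d(day length)/d(latitude)| falls below `cond_tol` or when |declination| is
#' below `decl_mask` (the equinox mask). Day lengths of 0 or 24 h admit no
#' solution and return reason `"polar"`.
#'
#' @param day_length observed day length in hours, in `[0, 24]`.
#' @param date calendar date (`Date` or string), or the `POSIXct` midpoint of
#'   the twilight pair (more accurate: declination is evaluated there).
#' @param a0 calibrated sun elevation angle in degrees (typically negative).
#' @param decl_mask equinox mask half-width in degrees of solar declination;
#'   the default 7 makes each seasonal mask span about 34 days.
#' @param cond_tol ill-conditioning tolerance in hours of day length per degree
#'   of latitude.
#' @return A one-row tibble: `lat` (degrees, `NA` when invalid), `valid`
#'   (logical), `reason` (`"ok"`, `"equinox"`, `"polar"`).
#' @export
latitude_from_daylength <- function(day_length, date, a0, decl_mask = 7,
                                    cond_tol = 0.01) {
  if (day_length < 0 || day_length > 24) {
    stop("day_length must lie in [0, 24] hours", call. = FALSE)
  }
  when <- if (inherits(date, "POSIXct")) {
    date
  } else {
    as.POSIXct(paste(as.Date(date), "12:00:00"), tz = "UTC")
  }
  decl <- solar_state(when)$declination
  if (day_length <= 0 || day_length >= 24) {
    return(tibble::tibble(lat = NA_real_, valid = FALSE, reason = "polar"))
  }
  # the seasonal mask applies regardless of whether a root exists: day length
  # carries no usable latitude signal this close to the equinox
  if (abs(decl) < decl_mask) {
    return(tibble::tibble(lat = NA_real_, valid = FALSE, reason = "equinox"))
  }
  d2r <- pi / 180
  model_dl <- function(phi) {
    x <- (sin(a0 * d2r) - sin(phi * d2r) * sin(decl * d2r)) /
      (cos(phi * d2r) * cos(decl * d2r))
    2 * acos(pmin(1, pmax(-1, x))) / d2r / 15
  }
  f <- function(phi) model_dl(phi) - day_length
  # With a negative a0 and |declination| < |a0| both poles sit in permanent
  # "day" above the threshold angle, so the day-length curve is non-monotone
  # in latitude and can have two roots; scan for sign changes and keep the
  # non-polar branch (smallest |latitude|).
  grid <- seq(-89.9, 89.9, by = 1)
  fg <- f(grid)
  sc <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (!length(sc)) {
    return(tibble::tibble(lat = NA_real_, valid = FALSE, reason = "polar"))
  }
  roots <- vapply(sc, function(j) {
    lo <- grid[j]
    hi <- grid[j + 1]
    for (i in 1:30) { # bisection to well under 0.01 degree
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < 0.005) break
    }
    (lo + hi) / 2
  }, numeric(1))
  phi <- roots[which.min(abs(roots))]
  sens <- abs(model_dl(phi + 0.5) - model_dl(phi - 0.5))
  if (sens < cond_tol) {
    return(tibble::tibble(lat = NA_real_, valid = FALSE, reason = "equinox"))
  }
  tibble::tibble(lat = phi, valid = TRUE, reason = "ok")
}

empty_positions <- function() {
  tibble::tibble(
    time = as.POSIXct(character(), tz = "UTC"), date = as.Date(character()),
    lon = numeric(), lat = numeric(), lat_valid = logical(),
    lat_reason = character(), lat_biased = logical(), source = character()
  )
}

# positions from an alternating twilight-event sequence
positions_from_events <- function(events, calib, decl_mask = 7,
                                  cond_tol = 0.01) {
  if (nrow(events) < 2) {
    return(empty_positions())
  }
  events <- events[order(events$time), ]
  n <- nrow(events) - 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e1 <- events[i, ]
    e2 <- events[i + 1, ]
    if (e1$kind == e2$kind) next
    gap_h <- as.numeric(difftime(e2$time, e1$time, units = "hours"))
    if (gap_h > 24) next
    day_pair <- e1$kind == "sunrise"
    mid <- e1$time + gap_h * 1800
    lon <- if (day_pair) {
      longitude_from_noon(e1$time, e2$time)
    } else {
      longitude_from_noon(e2$time, e1$time)
    }
    dl <- if (day_pair) gap_h else 24 - gap_h
    latr <- latitude_from_daylength(dl, mid, calib$a0,
      decl_mask = decl_mask, cond_tol = cond_tol
    )
    biased <- isTRUE(e1$elevated) || isTRUE(e2$elevated)
    out[[i]] <- tibble::tibble(
      time = mid, date = as.Date(mid), lon = lon,
      lat = latr$lat, lat_valid = latr$valid && !biased,
      lat_reason = if (biased) "polar-biased" else latr$reason,
      lat_biased = biased,
      source = if (day_pair) "noon" else "midnight"
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_positions() else res
}

#' Positions for polar-day periods via elevated thresholds
#'
#' During the austral-summer polar day the light series never crosses the
#' standard threshold. Re-detecting twilights with progressively higher
#' thresholds (by convention 40, then 100, mirroring the two logger families'
#' practice) recovers provisional "sunrise"/"sunset" pairs: the longitude
#' derived from their midpoint remains valid, while the shortened apparent day
#' lengths make the latitude biased equatorward by an unknown amount, so those
#' latitudes are flagged biased and excluded from latitude-based inference
#' other than "poleward of about 60S". Days crossing no threshold at all yield
#' no position.
#'
#' @param series light series tibble (`timestamp`, `light`).
#' @param calib a `calibration_model` (from [calibrate()]).
#' @param elevated_thresholds increasing ladder of elevated thresholds.
#' @param polar_dates `Date` vector of polar-candidate days to fill; defaults
#'   to the days with no standard-threshold crossing.
#' @param decl_mask,cond_tol passed to [latitude_from_daylength()].
#' @param min_gap_hours minimum day/night duration for the elevated-threshold
#'   detection. Deliberately short: near the polar circle the sun may dip
#'   below the elevated threshold angle for well under an hour around local
#'   midnight, and those provisional crossings are exactly what this fallback
#'   exists to capture.
#' @return Position tibble as in [locate_positions()], with `lat_biased = TRUE`.
#' @export
polar_positions <- function(series, calib, elevated_thresholds = c(40, 100),
                            polar_dates = NULL, decl_mask = 7,
                            cond_tol = 0.01, min_gap_hours = 0.5) {
  if (is.null(polar_dates)) {
    ev_std <- detect_twilights(series, calib$threshold)
    polar_dates <- attr(ev_std, "polar_candidate")
  }
  if (!length(polar_dates)) {
    return(empty_positions())
  }
  filled <- list(empty_positions())
  remaining <- polar_dates
  for (thr in sort(elevated_thresholds)) {
    if (!length(remaining)) break
    ev <- detect_twilights(series, thr,
      min_gap_hours = min_gap_hours, elevated = TRUE
    )
    pos <- positions_from_events(ev, calib, decl_mask, cond_tol)
    pos <- pos[pos$date %in% remaining, ]
    if (nrow(pos)) {
      filled[[length(filled) + 1]] <- pos
      remaining <- setdiff2_dates(remaining, unique(pos$date))
    }
  }
  dplyr::bind_rows(filled)
}

#' Twilight geolocation of a light series
#'
#' The full threshold-method chain for one deployment: detect twilights at the
#' calibrated standard threshold, convert each adjacent sunrise/sunset pair
#' into a noon or midnight position (two per day where the light regime
#' allows), and fill polar-day gaps with [polar_positions()] using the elevated
#' threshold ladder.
#'
#' @param series light series tibble (`timestamp`, `light`).
#' @param calib a `calibration_model`.
#' @param elevated_thresholds elevated threshold ladder for polar days; use
#'   `numeric(0)` to disable.
#' @param decl_mask,cond_tol latitude validity controls, see
#'   [latitude_from_daylength()].
#' @param min_gap_hours passed to [detect_twilights()].
#' @return A tibble of per-twilight-pair positions: `time`, `date`, `lon`,
#'   `lat`, `lat_valid`, `lat_reason`, `lat_biased`, `source`. Attribute
#'   `counts` records twilights detected/rejected, equinox-masked estimates and
#'   polar-candidate days.
#' @export
locate_positions <- function(series, calib, elevated_thresholds = c(40, 100),
                             decl_mask = 7, cond_tol = 0.01,
                             min_gap_hours = 2) {
  ev <- detect_twilights(series, calib$threshold, min_gap_hours)
  pos <- positions_from_events(ev, calib, decl_mask, cond_tol)
  polar_days <- attr(ev, "polar_candidate")
  ppos <- if (length(elevated_thresholds)) {
    polar_positions(series, calib, elevated_thresholds,
      polar_dates = polar_days, decl_mask = decl_mask, cond_tol = cond_tol
    )
  } else {
    empty_positions()
  }
  out <- dplyr::arrange(dplyr::bind_rows(pos, ppos), .data$time)
  attr(out, "counts") <- list(
    twilights = nrow(ev),
    twilights_rejected = nrow(attr(ev, "rejected")),
    equinox_masked = sum(out$lat_reason == "equinox"),
    polar_candidate_days = length(polar_days),
    polar_days_recovered = length(unique(ppos$date))
  )
  out
}
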