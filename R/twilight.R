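#' Detect twilight events by threshold crossing
#'
#' Sunrise and sunset are defined as the instants where the light series
#' crosses `threshold`, located by linear interpolation between adjacent
#' samples. Crossing pairs closer together than `min_gap_hours` (a day or night
#' shorter than any real one at the latitudes of interest) are treated as noise
#' spikes and removed. Calendar days (UTC) whose samples never cross the
#' threshold are flagged as polar candidates: either continuous daylight
#' (polar day at an elevated sun) or continuous darkness.
#'
#' @param series light series tibble with columns `timestamp` (`POSIXct`,
#'   sorted) and `light`.
#' @param threshold light threshold in instrument units (conventional standard
#'   value 2 on the canonical scale).
#' @param min_gap_hours minimum plausible day/night duration; closer crossing
#'   pairs are rejected.
#' @param elevated logical, marks the resulting events as obtained with an
#'   elevated polar threshold.
#' @return A tibble of events with columns `time`, `kind` (`"sunrise"` /
#'   `"sunset"`), `threshold`, `elevated`, `quality`; attributes
#'   `polar_candidate` (Dates with no crossing) and `rejected` (events removed
#'   by the minimum-gap rule, with a `reason` column).
#' @export
detect_twilights <- function(series, threshold = 2, min_gap_hours = 2,
                             elevated = FALSE) {
  stopifnot(all(c("timestamp", "light") %in% names(series)))
  if (nrow(series) < 2) stop("light series too short", call. = FALSE)
  if (is.unsorted(as.numeric(series$timestamp), strictly = FALSE)) {
    stop("light series timestamps must be sorted", call. = FALSE)
  }
  span <- as.numeric(difftime(
    max(series$timestamp), min(series$timestamp),
    units = "hours"
  ))
  if (span < 24) stop("light series must span at least one day", call. = FALSE)

  l <- series$light
  t <- as.numeric(series$timestamp)
  above <- l > threshold
  idx <- which(diff(above) != 0L)
  events <- if (length(idx)) {
    frac <- (threshold - l[idx]) / (l[idx + 1] - l[idx])
    tibble::tibble(
      time = as.POSIXct(t[idx] + frac * (t[idx + 1] - t[idx]),
        origin = "1970-01-01", tz = "UTC"
      ),
      kind = ifelse(above[idx + 1], "sunrise", "sunset"),
      threshold = threshold, elevated = elevated, quality = "ok"
    )
  } else {
    tibble::tibble(
      time = as.POSIXct(character(), tz = "UTC"), kind = character(),
      threshold = numeric(), elevated = logical(), quality = character()
    )
  }

  # iteratively drop crossing pairs closer than the minimum day/night duration
  rejected <- events[0, ]
  repeat {
    if (nrow(events) < 2) break
    gaps <- diff(as.numeric(events$time)) / 3600
    bad <- which(gaps < min_gap_hours)
    if (!length(bad)) break
    drop <- c(bad[1], bad[1] + 1)
    rej <- events[drop, ]
    rej$quality <- "rejected"
    rejected <- dplyr::bind_rows(rejected, rej)
    events <- events[-drop, ]
  }
  if (nrow(rejected)) rejected$reason <- "short day/night (noise spike)"

  all_days <- seq(as.Date(min(series$timestamp)), as.Date(max(series$timestamp)), by = 1)
  attr(events, "polar_candidate") <- setdiff2_dates(all_days, as.Date(events$time))
  attr(events, "rejected") <- rejected
  events
}

# setdiff on Dates that keeps the Date class
setdiff2_dates <- function(a, b) a[!(a %in% b)]

#' Calibrate the sun elevation angle at a known location
#'
#' The threshold method needs the solar elevation a0 that corresponds to the
#' light threshold on the deployed instrument. Following standard practice the
#' logger is calibrated over a window of clean light data at a known location
#' (the breeding colony): a0 is the median solar elevation, at the reference
#' position, over all detected twilight instants in the window.
#'
#' @param series light series tibble (`timestamp`, `light`).
#' @param lat,lon known reference position (degrees).
#' @param window length-2 `Date` vector (start, end), at least 5 days, lying
#'   within the series.
#' @param threshold light threshold the deployment will be processed with.
#' @param min_gap_hours passed to [detect_twilights()].
#' @return An object of class `calibration_model`: list with `a0` (degrees),
#'   `threshold`, `window`, `reference`, `n_events`.
#' @export
calibrate <- function(series, lat, lon, window, threshold = 2,
                      min_gap_hours = 2) {
  window <- as.Date(window)
  stopifnot(length(window) == 2)
  if (as.numeric(diff(window)) < 5) {
    stop("calibration window must span at least 5 days", call. = FALSE)
  }
  sel <- series$timestamp >= as.POSIXct(paste(window[1], "00:00:00"), tz = "UTC") &
    series$timestamp < as.POSIXct(paste(window[2] + 1, "00:00:00"), tz = "UTC")
  if (sum(sel) < 2) stop("calibration window lies outside the series", call. = FALSE)
  ev <- detect_twilights(series[sel, ], threshold, min_gap_hours)
  if (nrow(ev) < 10) {
    stop("fewer than 5 usable twilight pairs in the calibration window",
      call. = FALSE
    )
  }
  a0 <- stats::median(solar_elevation(ev$time, lat, lon))
  if (a0 <= -12 || a0 >= 2) {
    stop(sprintf(
      "calibrated sun angle %.2f deg outside the plausible (-12, 2) range",
      a0
    ), call. = FALSE)
  }
  structure(
    list(
      a0 = a0, threshold = threshold, window = window,
      reference = c(lat = lat, lon = lon), n_events = nrow(ev)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> a0 = %.2f deg at threshold %g (%d twilights, %s..%s at %.1f, %.1f)\n",
    x$a0, x$threshold, x$n_events, format(x$window[1]), format(x$window[2]),
    x$reference["lat"], x$reference["lon"]
  ))
  invisible(x)
}
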