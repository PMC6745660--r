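#' Unwrap a longitude series
#'
#' Adds or subtracts multiples of 360 degrees so that consecutive values differ
#' by less than 180 degrees, making a journey's longitude continuous across the
#' date line (an eastward passage through 180E continues 190, 200 ... rather
#' than jumping to -170). Idempotent. `NA`s are passed through.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return Unwrapped longitudes anchored at the first non-missing value.
#' @export
unwrap_longitude <- function(lon) {
  out <- lon
  idx <- which(!is.na(lon))
  if (length(idx) < 2) return(out)
  for (k in 2:length(idx)) {
    i <- idx[k]
    prev <- out[idx[k - 1]]
    out[i] <- lon[i] - 360 * round((lon[i] - prev) / 360)
  }
  out
}

# internal track constructor
new_track <- function(df, colony = c(lat = NA_real_, lon = NA_real_),
                      label = "track") {
  stopifnot(all(c("date", "lon", "lat", "lat_valid", "lat_biased", "n_sources")
  %in% names(df)))
  out <- tibble::as_tibble(df)
  attr(out, "colony") <- colony
  attr(out, "label") <- label
  class(out) <- c("tern_track", class(out))
  out
}

#' @export
print.tern_track <- function(x, ...) {
  colony <- attr(x, "colony")
  cat(sprintf(
    "<tern_track '%s'> %d days (%s..%s), colony %.1f, %.1f\n",
    attr(x, "label"), nrow(x), format(min(x$date)), format(max(x$date)),
    colony[1], colony[2]
  ))
  NextMethod()
}

#' Assemble per-twilight positions into one daily position per journey
#'
#' Averages the available noon/midnight estimates per UTC calendar day --- the
#' standard two-positions-per-day reduction that damps twilight-level scatter
#' and the latitude bias induced by longitudinal movement between twilights.
#' Longitudes straddling the date line are aligned before averaging, the daily
#' series is then unwrapped; a day's latitude is the mean of its valid
#' latitudes (or of its biased ones, kept flagged, when no valid estimate
#' exists); flags are propagated (any biased source makes the day biased).
#' Missing days are left missing: no interpolation.
#'
#' @param positions tibble from [locate_positions()].
#' @param colony length-2 `c(lat, lon)` of the breeding site.
#' @param label journey identifier.
#' @return A track tibble (class `tern_track`) with columns `date`, `lon`
#'   (unwrapped), `lat`, `lat_valid`, `lat_biased`, `n_sources`.
#' @export
assemble_track <- function(positions, colony = c(NA_real_, NA_real_),
                           label = "track") {
  daily <- positions |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      lon = mean_aligned_lon(.data$lon),
      lat = mean_daily_lat(.data$lat, .data$lat_valid, .data$lat_biased),
      lat_valid = any(.data$lat_valid),
      lat_biased = any(.data$lat_biased),
      n_sources = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$date)
  daily$lon <- unwrap_longitude(daily$lon)
  new_track(daily,
    colony = c(lat = unname(colony[1]), lon = unname(colony[2])),
    label = label
  )
}

# align longitudes to the first value modulo 360, then average; result wrapped
mean_aligned_lon <- function(lon) {
  lon <- lon[!is.na(lon)]
  if (!length(lon)) return(NA_real_)
  aligned <- lon - 360 * round((lon - lon[1]) / 360)
  wrap_lon(mean(aligned))
}

mean_daily_lat <- function(lat, valid, biased) {
  if (any(valid & !is.na(lat))) return(mean(lat[valid & !is.na(lat)]))
  if (any(biased & !is.na(lat))) return(mean(lat[biased & !is.na(lat)]))
  NA_real_
}

#' Read a logger light series
#'
#' Understands three dialects, auto-detected from the header unless forced:
#' `canonical` (`timestamp,light`, ISO-8601 UTC timestamps), `bas`
#' (`date,seconds_of_day,light,valid_flag`) and `intigeo`
#' (`timestamp,light_lux`; light is divided by `intigeo_scale` to return to the
#' canonical scale). Malformed rows are skipped with a message; more than 10%
#' malformed rows is an error.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"canonical"`, `"bas"` or `"intigeo"`.
#' @param intigeo_scale light-scale divisor for the intigeo dialect.
#' @return A tibble with columns `timestamp` (`POSIXct` UTC) and `light`.
#' @export
read_light <- function(path, dialect = c("auto", "canonical", "bas", "intigeo"),
                       intigeo_scale = 8) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty or header-only light file: ", path, call. = FALSE)
  header <- tolower(trimws(strsplit(lines[1], ",")[[1]]))
  if (dialect == "auto") {
    dialect <- if (identical(header, c("timestamp", "light"))) {
      "canonical"
    } else if (identical(header, c("date", "seconds_of_day", "light", "valid_flag"))) {
      "bas"
    } else if (identical(header, c("timestamp", "light_lux"))) {
      "intigeo"
    } else {
      stop("unrecognised light-file header: ", lines[1], call. = FALSE)
    }
  }
  body <- lines[-1]
  fields <- strsplit(body, ",", fixed = TRUE)
  if (dialect == "bas") {
    ok <- lengths(fields) == 4
    date <- as.Date(vapply(fields[ok], `[`, "", 1), optional = TRUE)
    secs <- suppressWarnings(as.numeric(vapply(fields[ok], `[`, "", 2)))
    light <- suppressWarnings(as.numeric(vapply(fields[ok], `[`, "", 3)))
    good <- !is.na(date) & !is.na(secs) & !is.na(light)
    ts <- as.POSIXct(paste(date[good], "00:00:00"), tz = "UTC") + secs[good]
    out <- tibble::tibble(timestamp = ts, light = light[good])
    n_bad <- length(body) - nrow(out)
  } else {
    ok <- lengths(fields) == 2
    ts <- suppressWarnings(as.POSIXct(vapply(fields[ok], `[`, "", 1),
      tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"
    ))
    ts2 <- suppressWarnings(as.POSIXct(vapply(fields[ok], `[`, "", 1), tz = "UTC"))
    ts[is.na(ts)] <- ts2[is.na(ts)]
    light <- suppressWarnings(as.numeric(vapply(fields[ok], `[`, "", 2)))
    good <- !is.na(ts) & !is.na(light)
    out <- tibble::tibble(timestamp = ts[good], light = light[good])
    if (dialect == "intigeo") out$light <- out$light / intigeo_scale
    n_bad <- length(body) - nrow(out)
  }
  if (n_bad > 0) {
    if (n_bad / length(body) > 0.10) {
      stop(sprintf(
        "%d of %d rows malformed (> 10%%) in %s", n_bad, length(body), path
      ), call. = FALSE)
    }
    message(sprintf("read_light: skipped %d malformed row(s) in %s", n_bad, path))
  }
  dplyr::arrange(out, .data$timestamp)
}

#' Write a light series
#'
#' @param series tibble with `timestamp`, `light`.
#' @param path output path.
#' @param dialect output dialect, see [read_light()].
#' @param intigeo_scale light-scale multiplier for the intigeo dialect.
#' @return `path`, invisibly.
#' @export
write_light <- function(series, path,
                        dialect = c("canonical", "bas", "intigeo"),
                        intigeo_scale = 8) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical") {
    df <- data.frame(
      timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      light = series$light
    )
  } else if (dialect == "bas") {
    df <- data.frame(
      date = format(as.Date(series$timestamp), "%Y-%m-%d"),
      seconds_of_day = as.numeric(series$timestamp) %% 86400,
      light = series$light,
      valid_flag = 1L
    )
  } else {
    df <- data.frame(
      timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      light_lux = series$light * intigeo_scale
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a daily-position track as CSV
#'
#' Fixed column set `date,lon,lat,lat_valid,lat_biased,n_sources`; the colony
#' and label are stored in comment header lines so a written track reads back
#' identically.
#'
#' @param track a `tern_track`.
#' @param path file path.
#' @return `path` (write) or a `tern_track` (read).
#' @export
write_track <- function(track, path) {
  colony <- attr(track, "colony")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", attr(track, "label")), con)
  writeLines(sprintf("# colony: %.6f,%.6f", colony[1], colony[2]), con)
  utils::write.csv(as.data.frame(track), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  label <- sub("^# label: ", "", grep("^# label:", meta, value = TRUE)[1])
  colony <- as.numeric(strsplit(
    sub("^# colony: ", "", grep("^# colony:", meta, value = TRUE)[1]), ","
  )[[1]])
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  df$date <- as.Date(df$date)
  df$lat_valid <- as.logical(df$lat_valid)
  df$lat_biased <- as.logical(df$lat_biased)
  new_track(df, colony = c(lat = colony[1], lon = colony[2]), label = label)
}
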