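#' Reported annual-cycle events of the 12 tracked Baltic journeys
#'
#' The per-journey phenology summary for the 12 annual journeys by eight
#' Baltic-colony arctic terns tracked with geolocators (journeys A1-H2,
#' 2008-2015): event dates as printed (day-month strings; approximate entries
#' such as `"beg June"` are kept verbatim and are excluded by [date_stats()]),
#' and the furthest-east longitude of each journey in unwrapped degrees east
#' (207 = 153W). These reported values serve as reference inputs for
#' summary statistics and cross-population comparison.
#'
#' @return A tibble with one row per journey: `journey`, `year`,
#'   `departure_breeding`, `natl_furthest_w`, `equator_crossing`, `pass_20e`,
#'   `pass_50s`, `furthest_e_date`, `furthest_e_lon`,
#'   `antarctic_furthest_w_date`, `antarctic_furthest_w_lon`,
#'   `arrival_breeding`.
#' @export
baltic_journey_events <- function() {
  tibble::tibble(
    journey = c(
      "A1", "A2", "B", "C", "D", "E1", "E2", "F", "G1", "G2", "H1", "H2"
    ),
    year = c(2008, 2009, 2008, 2009, 2009, 2011, 2012, 2011, 2013, 2014, 2014, 2015),
    departure_breeding = c(
      "13 July", "9 July", "7 July", "21 July", "11 July", "24 July",
      "beg June", "28 July", "21 July", "9 July", "10 July", "15 July"
    ),
    natl_furthest_w = c(
      "28 July", "18 July", "29 July", "8 August", "27 July", "8 August",
      "20 July", "9 August", "30 July", "30 July", "30 July", "29 July"
    ),
    equator_crossing = c(
      "13 August", "6 August", "13 August", "20 August", "12 August",
      "28 August", "c. 30 July", "29 August", "9 August", "8 August",
      "10 August", "8 August"
    ),
    pass_20e = c(
      "2 September", "12 September", "28 August", "2 September",
      "21-29 August", "8 September", "Mid-August", "28 September",
      "13 September", "5 September", "6 September", "26 August"
    ),
    pass_50s = c(
      "29 October", "8 November", "8 November", "2 November", "27 October",
      "beg October to beg November", "c. 29 October", "6 November",
      "31 October", "4 November", "4 November", "25 October"
    ),
    furthest_e_date = c(
      "7 November", "27 November", "29 October", "3 November", "30 October",
      "11 November", "16 November", "6 November", "15 November", "7 November",
      "4 November", "30 October"
    ),
    furthest_e_lon = c(152, 158, 167, 122, 89, 158, 207, 122, 157, 153, 101, 101),
    antarctic_furthest_w_date = c(
      "11 March", NA, NA, NA, "13 March", "13 March", NA, NA, "22 March",
      NA, "9 March", NA
    ),
    antarctic_furthest_w_lon = c(23, NA, NA, NA, -32, -40, NA, NA, -42, NA, -45, NA),
    arrival_breeding = c(
      "24 April", NA, NA, NA, "30 April", NA, NA, NA, "26 April", NA,
      "26 April", NA
    )
  )
}

#' Schematic waypoint chains of the annual migration circuit
#'
#' The mean migration circuit of the tracked Baltic terns as seven dated
#' loxodrome waypoint chains (breeding area 56N 14.5E; mean event dates and
#' mean locations), plus the minimum and maximum variants of the Indian Ocean
#' and Antarctic segments recorded among journeys. Dates carry explicit years
#' so that durations follow directly.
#'
#' @param variant `"mean"` (the seven-segment circuit), `"min"` or `"max"`
#'   (the shortest/longest recorded Indian Ocean and Antarctic alternatives).
#' @param start_year year of the July departure used to date the chains.
#' @return A list of [segment_spec()] objects.
#' @export
tern_circuit_segments <- function(variant = c("mean", "min", "max"),
                                  start_year = 2008) {
  variant <- match.arg(variant)
  y0 <- start_year
  y1 <- start_year + 1
  d <- function(y, md) as.Date(sprintf("%d-%s", y, md))
  wp <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(lat = m[, 1], lon = m[, 2])
  }
  if (variant == "mean") {
    list(
      segment_spec(
        "Breeding area - N Atlantic", wp(56, 14.5, 43, -31),
        d(y0, "07-15"), d(y0, "07-29")
      ),
      segment_spec(
        "N Atlantic - Equator", wp(43, -31, 0, -13, 0, 5),
        d(y0, "07-29"), d(y0, "08-12")
      ),
      segment_spec(
        "Equator - South Africa", wp(0, 5, -36, 20),
        d(y0, "08-12"), d(y0, "09-06")
      ),
      segment_spec(
        "South Africa - Antarctica", wp(-36, 20, -40, 100, -65, 141),
        d(y0, "09-06"), d(y0, "11-07")
      ),
      segment_spec(
        "Antarctica, E to W", wp(-65, 141, -65, -27),
        d(y0, "11-07"), d(y1, "03-13")
      ),
      segment_spec(
        "Antarctica - N Atlantic", wp(-65, -27, -30, 5, 34, -34),
        d(y1, "03-13"), d(y1, "04-10")
      ),
      segment_spec(
        "N Atlantic - breeding area", wp(34, -34, 56, 14.5),
        d(y1, "04-10"), d(y1, "04-26")
      )
    )
  } else if (variant == "min") {
    list(
      segment_spec(
        "South Africa - Antarctica (min)", wp(-36, 20, -40, 75, -65, 89),
        d(y0, "09-06"), d(y0, "11-07")
      ),
      segment_spec(
        "Antarctica, E to W (min)", wp(-65, 89, -65, -27),
        d(y0, "11-07"), d(y1, "03-13")
      )
    )
  } else {
    list(
      segment_spec(
        "South Africa - Antarctica (max)", wp(-36, 20, -40, 160, -65, 207),
        d(y0, "09-06"), d(y0, "11-07")
      ),
      segment_spec(
        "Antarctica, E to W (max)", wp(-65, 207, -65, -27),
        d(y0, "11-07"), d(y1, "03-13")
      )
    )
  }
}

#' Distance/duration/speed table for the schematic circuit
#'
#' Evaluates [chain_distance()] over the circuit segments and appends the
#' full-circuit total (legs of all segments summed, duration from first
#' departure to final arrival). With `report = TRUE`, distances are rounded to
#' the nearest 10 km and speeds to 1 km/day, and each chain is assembled from
#' legs individually rounded to 10 km -- the convention of the original
#' schematic table.
#'
#' @param segments list of [segment_spec()]s, e.g. [tern_circuit_segments()].
#' @param report apply report rounding (and per-leg rounding in the chains).
#' @return A tibble with columns `name`, `start`, `end`, `duration_days`,
#'   `distance_km`, `speed_km_day`; the last row is the total circuit.
#' @export
circuit_table <- function(segments = tern_circuit_segments(), report = TRUE) {
  rows <- purrr::map_dfr(segments, chain_distance, round_legs = report)
  total_dist <- sum(purrr::map_dbl(
    segments,
    \(s) chain_distance(s)$distance_km # total from unrounded legs
  ))
  total_dur <- as.numeric(max(rows$end) - min(rows$start))
  total <- tibble::tibble(
    name = "Total nonbreeding migration circuit",
    start = min(rows$start), end = max(rows$end),
    duration_days = total_dur, distance_km = total_dist,
    speed_km_day = total_dist / total_dur
  )
  out <- dplyr::bind_rows(rows, total)
  if (report) round_segments(out) else out
}
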