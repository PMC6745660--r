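#' Longitude-versus-date plot of a journey
#'
#' The standard diagnostic for these tracks: unwrapped longitude against date,
#' with latitude-invalid days (equinox mask) hollow and polar-biased days in a
#' different shape, optionally annotated with detected events.
#'
#' @param track a `tern_track`.
#' @param events optional one-row event tibble from [detect_events()].
#' @return A ggplot object.
#' @export
plot_longitude <- function(track, events = NULL) {
  df <- tibble::as_tibble(track)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$lon)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$lat_biased, alpha = .data$lat_valid),
      size = 1.2
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35), guide = "none") +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 17),
      name = "polar-biased latitude"
    ) +
    ggplot2::labs(
      x = NULL, y = "longitude (degrees E, unwrapped)",
      title = attr(track, "label")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    dates <- suppressWarnings(as.Date(unlist(lapply(
      events[grep("date|departure|crossing|pass|arrival", names(events))],
      as.character
    ))))
    dates <- dates[!is.na(dates)]
    if (length(dates)) {
      p <- p + ggplot2::geom_vline(
        xintercept = dates,
        linetype = "dotted", colour = "firebrick"
      )
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.tern_track <- function(object, ...) plot_longitude(object, ...)

#' Plot detected stopovers as longitude intervals
#'
#' @param stopovers tibble from [detect_stopovers()] (optionally several
#'   journeys bound together with a `journey` column).
#' @return A ggplot object.
#' @export
plot_stopovers <- function(stopovers) {
  df <- stopovers
  if (!"journey" %in% names(df)) df$journey <- "journey"
  ggplot2::ggplot(df, ggplot2::aes(
    y = .data$journey, x = .data$lon_min, xend = .data$lon_max,
    yend = .data$journey
  )) +
    ggplot2::geom_segment(linewidth = 2, colour = "steelblue") +
    ggplot2::labs(
      x = "longitude interval (degrees E)", y = NULL,
      title = "stopovers (longitude change ≤ 1 degree/day)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a few days of a light series
#'
#' @param series light series tibble (`timestamp`, `light`).
#' @param days number of days to show from the start.
#' @param threshold optional horizontal threshold line.
#' @return A ggplot object.
#' @export
plot_light <- function(series, days = 5, threshold = 2) {
  sel <- series$timestamp <= min(series$timestamp) + days * 86400
  ggplot2::ggplot(series[sel, ], ggplot2::aes(x = .data$timestamp, y = .data$light)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "light (instrument units)") +
    ggplot2::theme_minimal()
}
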