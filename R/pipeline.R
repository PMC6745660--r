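#' Pipeline configuration
#'
#' All tunable parameters of the light-to-report chain with their documented
#' defaults: the standard twilight threshold (2 canonical units), the elevated
#' polar-day ladder (40 then 100), a 10-day breeding-area calibration window,
#' the equinox mask and conditioning tolerance for latitude, the minimum
#' day/night duration, event-detection thresholds, the stopover criterion
#' (at most 1 degree of longitude per day for at least 5 days), and report
#' rounding. A config round-trips through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param standard_threshold standard light threshold (instrument units).
#' @param elevated_thresholds elevated threshold ladder for polar days.
#' @param calib_window_days length of the breeding-area calibration window.
#' @param decl_mask,cond_tol latitude validity controls
#'   ([latitude_from_daylength()]).
#' @param min_gap_hours minimum plausible day/night duration.
#' @param sim_step_hours trajectory interpolation step used when simulating.
#' @param stopover_rate_max,stopover_min_days stopover criterion.
#' @param events an [event_config()].
#' @param light a [light_model()] used when simulating from a scenario.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(standard_threshold = 2,
                            elevated_thresholds = c(40, 100),
                            calib_window_days = 10,
                            decl_mask = 7, cond_tol = 0.01,
                            min_gap_hours = 2, sim_step_hours = 6,
                            stopover_rate_max = 1.0, stopover_min_days = 5,
                            events = event_config(),
                            light = light_model()) {
  structure(
    list(
      standard_threshold = standard_threshold,
      elevated_thresholds = elevated_thresholds,
      calib_window_days = calib_window_days,
      decl_mask = decl_mask, cond_tol = cond_tol,
      min_gap_hours = min_gap_hours, sim_step_hours = sim_step_hours,
      stopover_rate_max = stopover_rate_max,
      stopover_min_days = stopover_min_days,
      events = events, light = light
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config
  flat$events <- unclass(config$events)
  flat$light <- unclass(config$light)
  yaml::write_yaml(unclass(flat), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    standard_threshold = y$standard_threshold,
    elevated_thresholds = unlist(y$elevated_thresholds),
    calib_window_days = y$calib_window_days,
    decl_mask = y$decl_mask, cond_tol = y$cond_tol,
    min_gap_hours = y$min_gap_hours, sim_step_hours = y$sim_step_hours,
    stopover_rate_max = y$stopover_rate_max,
    stopover_min_days = y$stopover_min_days,
    events = do.call(event_config, y$events),
    light = do.call(light_model, y$light)
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full light-to-report pipeline
#'
#' Orchestrates the stages simulate (optional) -> twilight detection ->
#' calibration -> positions -> daily track -> events, stopovers, Convergence
#' displacement and monthly ranges -> schematic route metrics, and collects a
#' structured log of counts (twilights detected and rejected, equinox-masked
#' estimates, polar-candidate and recovered days). Either a scenario (to
#' simulate a deployment) or a recorded light series must be supplied.
#'
#' @param scenario a [trajectory_scenario()] to simulate from, or `NULL`.
#' @param light a light series tibble (`timestamp`, `light`) or a file path
#'   readable by [read_light()]; ignored when `scenario` is given.
#' @param colony breeding-site `c(lat, lon)`; defaults to the scenario's.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the simulation stage.
#' @param out_dir if non-`NULL`, every stage's output is written there
#'   (CSV intermediates plus `report.json` and `report.txt`).
#' @return An object of class `tern_pipeline`: list with `light`, `calibration`,
#'   `positions`, `track`, `events`, `stopovers`, `convergence`, `monthly`,
#'   `segments`, `log`.
#' @export
run_pipeline <- function(scenario = NULL, light = NULL, colony = NULL,
                         config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.null(scenario) && is.null(light)) {
    stop("supply a scenario or a light series", call. = FALSE)
  }
  label <- "deployment"
  if (!is.null(scenario)) {
    label <- scenario$label
    colony <- colony %||% scenario$colony
    series <- run_stage("simulate", {
      traj <- interpolate_trajectory(scenario,
        step_hours = config$sim_step_hours, seed = seed
      )
      simulate_light(traj, config$light, seed = seed)
    })
  } else {
    if (is.character(light)) {
      series <- run_stage("read_light", read_light(light))
      label <- sub("\\.[^.]*$", "", basename(light))
    } else {
      series <- light
    }
    if (is.null(colony)) stop("`colony` is required with recorded light", call. = FALSE)
  }
  calib <- run_stage("calibrate", {
    w0 <- as.Date(min(series$timestamp))
    calibrate(series, unname(colony[1]), unname(colony[2]),
      window = c(w0, w0 + config$calib_window_days),
      threshold = config$standard_threshold,
      min_gap_hours = config$min_gap_hours
    )
  })
  positions <- run_stage("positions", locate_positions(
    series, calib,
    elevated_thresholds = config$elevated_thresholds,
    decl_mask = config$decl_mask, cond_tol = config$cond_tol,
    min_gap_hours = config$min_gap_hours
  ))
  track <- run_stage("track", assemble_track(positions, colony, label))
  events <- run_stage("events", detect_events(track, config$events))
  stopovers <- run_stage("stopovers", detect_stopovers(
    track, events$pass_20e, events$pass_50s,
    rate_max = config$stopover_rate_max, min_days = config$stopover_min_days
  ))
  convergence <- run_stage(
    "convergence",
    convergence_displacement(track, events$pass_50s)
  )
  monthly <- run_stage("monthly", monthly_ranges(
    track, events$pass_50s, events$departure_antarctica
  ))
  segments <- run_stage("distances", circuit_table(report = TRUE))
  log <- c(attr(positions, "counts"), list(
    days_tracked = nrow(track),
    stopovers = nrow(stopovers)
  ))
  res <- structure(
    list(
      light = series, calibration = calib, positions = positions,
      track = track, events = events, stopovers = stopovers,
      convergence = convergence, monthly = monthly, segments = segments,
      log = log, seed = seed
    ),
    class = "tern_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_light(res$light, file.path(out_dir, "light.csv"))
  utils::write.csv(
    dplyr::mutate(res$positions,
      time = format(.data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ),
    file.path(out_dir, "positions.csv"),
    row.names = FALSE
  )
  write_track(res$track, file.path(out_dir, "track.csv"))
  utils::write.csv(res$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(res$stopovers, file.path(out_dir, "stopovers.csv"), row.names = FALSE)
  utils::write.csv(res$segments, file.path(out_dir, "segments.csv"), row.names = FALSE)
  report <- list(
    calibration = list(
      a0_deg = res$calibration$a0,
      threshold = res$calibration$threshold
    ),
    log = res$log,
    events = as.list(dplyr::mutate(res$events, dplyr::across(
      dplyr::where(\(x) inherits(x, "Date")), format
    ))),
    convergence = as.list(dplyr::mutate(res$convergence, dplyr::across(
      dplyr::where(\(x) inherits(x, "Date")), format
    ))),
    segments = lapply(seq_len(nrow(res$segments)), function(i) {
      as.list(dplyr::mutate(res$segments[i, ], dplyr::across(
        dplyr::where(\(x) inherits(x, "Date")), format
      )))
    }),
    seed = res$seed
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  txt <- utils::capture.output(print(res))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.tern_pipeline <- function(x, ...) {
  cat("== ternlight pipeline report ==\n")
  print(x$calibration)
  cat(sprintf(
    "twilights: %d detected, %d rejected; %d equinox-masked estimates; %d polar-candidate days (%d recovered at elevated thresholds)\n",
    x$log$twilights, x$log$twilights_rejected, x$log$equinox_masked,
    x$log$polar_candidate_days, x$log$polar_days_recovered
  ))
  cat(sprintf("daily track: %d days\n", x$log$days_tracked))
  cat("\n-- events --\n")
  ev <- tidyr::pivot_longer(
    dplyr::mutate(x$events, dplyr::across(dplyr::everything(), as.character)),
    -"journey",
    names_to = "event", values_to = "value"
  )
  print(as.data.frame(ev), row.names = FALSE)
  cat("\n-- stopovers --\n")
  print(as.data.frame(x$stopovers), row.names = FALSE)
  cat("\n-- Antarctic Convergence crossing --\n")
  print(as.data.frame(x$convergence), row.names = FALSE)
  cat("\n-- schematic circuit (distances to 10 km, speeds to 1 km/day) --\n")
  print(as.data.frame(x$segments[, c(
    "name", "duration_days", "distance_km",
    "speed_km_day"
  )]), row.names = FALSE)
  invisible(x)
}
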