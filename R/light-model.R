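#' Logger light-transfer model
#'
#' Describes how a light logger converts solar elevation into the stored light
#' value: a monotone sigmoid in solar elevation with saturation, additive
#' Gaussian sensor noise, and optional per-sample shading (Bernoulli
#' attenuation, emulating a bird tucking the sensor under a wing or sitting in
#' shadow). Three output dialects mirror common logger families: `canonical`
#' (`timestamp,light` CSV), `bas` (`date,seconds_of_day,light,valid_flag`) and
#' `intigeo` (canonical columns on a rescaled light axis).
#'
#' Defaults: 5-minute sampling, sigmoid located at -3 degrees solar elevation
#' with 1 degree scale, saturation at 120 units, sensor noise SD 0.5 units
#' (about a minute of twilight-timing jitter), no shading. On this scale the
#' conventional twilight threshold is 2 units and the elevated polar-day
#' ladder is 40 then 100 units.
#'
#' @param interval_min sampling interval in minutes; must divide 24 h.
#' @param location,scale sigmoid location and scale in degrees of solar
#'   elevation. `scale > 0`; light is monotonically non-decreasing in
#'   elevation.
#' @param clip_max saturation level (instrument units).
#' @param noise_sd additive noise SD (instrument units); output is clipped at 0.
#' @param shading_prob,shading_factor per-sample probability of a shading event
#'   and the multiplicative attenuation applied when one occurs.
#' @param dialect output dialect: `"canonical"`, `"bas"` or `"intigeo"`.
#' @param intigeo_scale multiplier applied to light values in the intigeo
#'   dialect.
#' @return An object of class `light_model`.
#' @export
light_model <- function(interval_min = 5, location = -3, scale = 1,
                        clip_max = 120, noise_sd = 0.5, shading_prob = 0,
                        shading_factor = 0.1,
                        dialect = c("canonical", "bas", "intigeo"),
                        intigeo_scale = 8) {
  dialect <- match.arg(dialect)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (clip_max <= 0) stop("`clip_max` must be positive", call. = FALSE)
  if ((24 * 60) %% interval_min != 0) {
    stop("`interval_min` must divide 24 hours", call. = FALSE)
  }
  if (shading_prob < 0 || shading_prob > 1) {
    stop("`shading_prob` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      interval_min = interval_min, location = location, scale = scale,
      clip_max = clip_max, noise_sd = noise_sd, shading_prob = shading_prob,
      shading_factor = shading_factor, dialect = dialect,
      intigeo_scale = intigeo_scale
    ),
    class = "light_model"
  )
}

#' @export
print.light_model <- function(x, ...) {
  cat("<light_model>\n")
  cat(sprintf(
    "  sampling %d min; sigmoid(location %.1f deg, scale %.1f deg), clip %.0f\n",
    x$interval_min, x$location, x$scale, x$clip_max
  ))
  cat(sprintf(
    "  noise sd %.2f; shading p=%.2f x%.2f; dialect %s\n",
    x$noise_sd, x$shading_prob, x$shading_factor, x$dialect
  ))
  invisible(x)
}

#' Noiseless light transfer: solar elevation to instrument units
#'
#' @param model a [light_model()].
#' @param elevation solar elevation in degrees.
#' @return Light level in instrument units (before noise/shading/clipping).
#' @export
light_transfer <- function(model, elevation) {
  model$clip_max / (1 + exp(-(elevation - model$location) / model$scale))
}

#' Solar elevation corresponding to a light threshold
#'
#' Inverse of [light_transfer()]; the theoretical sun angle a0 at which a
#' noiseless logger crosses `threshold`. Useful for checking calibration.
#'
#' @inheritParams light_transfer
#' @param threshold light threshold (instrument units); must lie strictly
#'   inside `(0, clip_max)`.
#' @return Elevation in degrees.
#' @export
threshold_elevation <- function(model, threshold) {
  if (any(threshold <= 0 | threshold >= model$clip_max)) {
    stop("`threshold` must lie strictly between 0 and clip_max", call. = FALSE)
  }
  model$location - model$scale * log(model$clip_max / threshold - 1)
}
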