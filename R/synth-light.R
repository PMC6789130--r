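# Forward model of an archival light logger: clipped monotone map of solar
# elevation with optional twilight-time jitter and shading, and total
# darkness on days the bird incubates inside its nesting cave.

#' Simulate a logger light series from a behaviour schedule
#'
#' Light is a clipped linear map of geometric solar elevation `e` at the
#' bird's daily position: 0 below the ramp, the sensor maximum (64) above
#' it, and a single linear ramp of width `ramp` degrees between, anchored
#' so that light equals `threshold` exactly when `e == ea_true`. The
#' calibration problem is thereby well posed: the elevation recovered by
#' thresholding at `threshold` is the device's true sun elevation angle,
#' and the constant ramp slope keeps threshold-crossing interpolation
#' unbiased.
#'
#' Noise enters as Gaussian jitter of the twilight transition times (the
#' light curve near each sunrise/sunset is evaluated at a time shifted by a
#' per-event draw), mimicking shading/behavioural interference at dawn and
#' dusk. Days spent incubating in the cave (`cave_day`) record zero light
#' throughout.
#'
#' @param schedule a [simulate_schedule()] object.
#' @param ea_true device sun elevation angle in degrees, in `[-9, 0]`.
#' @param jitter_sd SD of twilight-time jitter, minutes (0 = noiseless).
#' @param cadence sampling interval in minutes (>= 1).
#' @param ramp full width of the light ramp in elevation degrees.
#' @param threshold light value mapped to `ea_true` (default 10).
#' @param shading_prob per-day probability of a random daytime shading
#'   event (light forced to 0 for 30-120 min); default 0.
#' @param seed integer seed for the noise draws (optional).
#' @return A data.frame of class `light_series` with columns `timestamp`
#'   (`POSIXct` UTC) and `light` (0-64), and attributes `bird_id`,
#'   `cadence`.
#' @export
simulate_light <- function(schedule, ea_true = -3.5, jitter_sd = 0,
                           cadence = 5, ramp = 4, threshold = 10,
                           shading_prob = 0, seed = NULL) {
  stopifnot(inherits(schedule, "behavior_schedule"))
  if (ea_true < -9 || ea_true > 0) stop("`ea_true` must be in [-9, 0]")
  if (cadence < 1) stop("`cadence` must be >= 1 minute")
  days <- schedule$days
  gaps <- diff(days$date)
  if (any(gaps != 1)) {
    stop("schedule has gaps after: ",
         paste(days$date[which(gaps != 1)], collapse = ", "))
  }

  .with_seed(seed, {
    t0 <- as.POSIXct(as.character(days$date[1]), tz = "UTC")
    t1 <- as.POSIXct(as.character(days$date[nrow(days)]), tz = "UTC") + 86400 - cadence * 60
    ts <- seq(t0, t1, by = cadence * 60)
    day_idx <- findInterval(as.numeric(ts), as.numeric(as.POSIXct(as.character(days$date), tz = "UTC")))
    lon <- days$lon[day_idx]
    lat <- days$lat[day_idx]

    eval_time <- ts
    if (jitter_sd > 0) {
      tw <- twilight_times(days$date, days$lon, days$lat, ea = ea_true)
      d_sr <- stats::rnorm(nrow(days), 0, jitter_sd) * 60
      d_ss <- stats::rnorm(nrow(days), 0, jitter_sd) * 60
      win <- 5400  # +/- 90 min around each event
      sr <- tw$sunrise[day_idx]
      ss <- tw$sunset[day_idx]
      shift <- numeric(length(ts))
      near_sr <- !is.na(sr) & abs(as.numeric(ts) - as.numeric(sr)) < win
      near_ss <- !is.na(ss) & abs(as.numeric(ts) - as.numeric(ss)) < win
      shift[near_sr] <- d_sr[day_idx][near_sr]
      shift[near_ss] <- d_ss[day_idx][near_ss]
      eval_time <- ts - shift
    }

    elev <- solar_elevation(eval_time, lon, lat)

    lo <- ea_true - ramp * threshold / 64
    light <- pmin(64, pmax(0, 64 * (elev - lo) / ramp))

    # incubation days: bird inside the cave, zero light all day
    cave_dates <- days$date[days$cave_day]
    if (length(cave_dates)) {
      light[days$date[day_idx] %in% cave_dates] <- 0
    }

    if (shading_prob > 0) {
      shade_days <- which(stats::runif(nrow(days)) < shading_prob & !days$cave_day)
      for (i in shade_days) {
        start <- as.numeric(as.POSIXct(as.character(days$date[i]), tz = "UTC")) +
          stats::runif(1, 8, 15) * 3600
        len <- stats::runif(1, 30, 120) * 60
        light[as.numeric(ts) >= start & as.numeric(ts) <= start + len] <- 0
      }
    }

    structure(
      data.frame(timestamp = ts, light = round(light, 3)),
      class = c("light_series", "data.frame"),
      bird_id = schedule$bird_id, cadence = cadence
    )
  })
}
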