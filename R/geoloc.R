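# Threshold light-level geolocation: twilight detection, position
# estimation from twilight midpoint (longitude) and day/night length
# (latitude), per-device sun-elevation-angle calibration, and the
# filtering cascade (equinox windows, latitude bounds, speed).

.wrap_lon <- function(x) ((x + 180) %% 360) - 180

#' Detect twilights in a light series
#'
#' Locates threshold crossings of the light trace by linear interpolation
#' between adjacent samples, removes implausible short dark periods
#' (artifacts such as mid-day shading; true nights at seabird latitudes are
#' always longer), and pairs the remaining transitions into per-day light
#' ("day") pairs and dark ("night") pairs.
#'
#' @param series data.frame with columns `timestamp` (`POSIXct` UTC) and
#'   `light` (e.g. from [simulate_light()] or [read_light_csv()]).
#' @param threshold light threshold defining twilight (default 10).
#' @param min_dark_hours dark periods shorter than this are flagged
#'   `short_dark` and excluded from pairing (default 4 h).
#' @param min_light_hours light periods shorter than this are treated as
#'   night-time interference spikes and excluded (default 1 h).
#' @return data.frame of class `twilight_pairs` with columns `date` (civil
#'   date of the pair midpoint), `type` (`"day"`: sunrise then sunset of one
#'   light day; `"night"`: sunset then next sunrise), `sunrise`, `sunset`
#'   (`POSIXct` UTC) and `quality` (`"ok"` or `"interference"` when a
#'   removed artifact bordered the pair). Zero rows (with a warning) when
#'   the series never crosses the threshold.
#' @export
detect_twilights <- function(series, threshold = 10, min_dark_hours = 4,
                             min_light_hours = 1) {
  if (!all(c("timestamp", "light") %in% names(series))) {
    stop("`series` must have columns `timestamp` and `light`")
  }
  if (nrow(series) == 0) stop("empty light series")
  if (diff(range(as.numeric(series$timestamp))) < 86400) {
    stop("light series must span at least one full day")
  }
  t <- as.numeric(series$timestamp)
  l <- series$light
  above <- l > threshold
  chg <- which(diff(above) != 0)
  if (length(chg) == 0) {
    warning("light never crosses the threshold; no twilights detected")
    return(structure(
      data.frame(date = as.Date(character(0)), type = character(0),
                 sunrise = as.POSIXct(character(0), tz = "UTC"),
                 sunset = as.POSIXct(character(0), tz = "UTC"),
                 quality = character(0)),
      class = c("twilight_pairs", "data.frame")))
  }
  frac <- (threshold - l[chg]) / (l[chg + 1] - l[chg])
  t_cross <- t[chg] + frac * (t[chg + 1] - t[chg])
  rising <- !above[chg]   # dark -> light: sunrise

  ev <- data.frame(time = t_cross, rising = rising)
  ev <- ev[order(ev$time), ]

  # drop short light spikes (night interference) and short dark artifacts
  # (day shading); neighbours of removed events inherit an interference flag
  tainted <- rep(FALSE, nrow(ev))
  repeat {
    n <- nrow(ev)
    if (n < 2) break
    dur <- diff(ev$time)
    is_light <- ev$rising[-n]           # interval after a rising event is light
    bad <- which((is_light & dur < min_light_hours * 3600) |
                   (!is_light & dur < min_dark_hours * 3600))
    if (length(bad) == 0) break
    b <- bad[1]
    keep <- setdiff(seq_len(n), c(b, b + 1))
    tainted_new <- tainted[keep]
    # mark surviving neighbours
    prev_idx <- which(keep < b)
    next_idx <- which(keep > b + 1)
    if (length(prev_idx)) tainted_new[max(prev_idx)] <- TRUE
    if (length(next_idx)) tainted_new[min(next_idx)] <- TRUE
    ev <- ev[keep, ]
    tainted <- tainted_new
  }

  pairs <- list()
  n <- nrow(ev)
  for (i in seq_len(n - 1)) {
    t1 <- ev$time[i]; t2 <- ev$time[i + 1]
    if (ev$rising[i] && !ev$rising[i + 1]) type <- "day"
    else if (!ev$rising[i] && ev$rising[i + 1]) type <- "night"
    else next
    mid <- (t1 + t2) / 2
    q <- if (tainted[i] || tainted[i + 1]) "interference" else "ok"
    pairs[[length(pairs) + 1]] <- data.frame(
      date = as.Date(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC")),
      type = type,
      sunrise = as.POSIXct(if (type == "day") t1 else t2,
                           origin = "1970-01-01", tz = "UTC"),
      sunset = as.POSIXct(if (type == "day") t2 else t1,
                          origin = "1970-01-01", tz = "UTC"),
      quality = q
    )
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  structure(out, class = c("twilight_pairs", "data.frame"))
}

#' Estimate positions from twilight pairs
#'
#' The threshold method: longitude from the local solar noon (or midnight)
#' implied by the twilight midpoint and the equation of time; latitude from
#' day (or night) length by solving
#' `sin(ea) = sin(lat) sin(decl) + cos(lat) cos(decl) cos(H0)`
#' for the latitude, where `H0` is the half-day hour angle and `ea` the
#' calibrated sun elevation angle.
#'
#' Latitude is returned missing (`lat_status`) when the hour-angle equation
#' has no solution at any latitude (`"unsolvable"`) or when the day length
#' is within `eps_hours` of 12 h, where latitude is unidentifiable
#' (`"indeterminate"`, the equinox degeneracy).
#'
#' @param pairs a [detect_twilights()] data.frame (rows with
#'   `quality != "ok"` are skipped).
#' @param ea sun elevation angle in degrees (|ea| <= 9).
#' @param eps_hours day-length window around 12 h treated as degenerate.
#' @return data.frame of class `geo_fixes`: `date`, `time` (pair midpoint),
#'   `type`, `lon`, `lat`, `lat_status`, `filters` (empty string),
#'   `retained` (`TRUE`).
#' @export
position_from_twilights <- function(pairs, ea, eps_hours = 0.1) {
  if (abs(ea) > 9) stop("|ea| must be <= 9 degrees")
  pairs <- pairs[pairs$quality == "ok", , drop = FALSE]
  n <- nrow(pairs)
  if (n == 0) {
    return(structure(
      data.frame(date = as.Date(character(0)),
                 time = as.POSIXct(character(0), tz = "UTC"),
                 type = character(0), lon = numeric(0), lat = numeric(0),
                 lat_status = character(0), filters = character(0),
                 retained = logical(0)),
      class = c("geo_fixes", "data.frame")))
  }
  t1 <- as.numeric(pairs$sunrise)
  t2 <- as.numeric(pairs$sunset)
  mid <- as.POSIXct((t1 + t2) / 2, origin = "1970-01-01", tz = "UTC")
  dur_h <- abs(t2 - t1) / 3600
  day_len <- ifelse(pairs$type == "day", dur_h, 24 - dur_h)

  sp <- solar_position(mid)
  mins <- (as.numeric(mid) %% 86400) / 60
  lon <- .wrap_lon((720 - sp$eot - mins) / 4 +
                     ifelse(pairs$type == "night", 180, 0))

  h0 <- .deg2rad(7.5 * day_len)
  decl <- .deg2rad(sp$declination)
  a <- sin(decl)
  b <- cos(decl) * cos(h0)
  r <- sqrt(a^2 + b^2)
  theta <- atan2(a, b)
  arg <- sin(.deg2rad(ea)) / r
  lat <- rep(NA_real_, n)
  status <- rep("ok", n)
  solvable <- abs(arg) <= 1
  acs <- acos(pmin(1, pmax(-1, arg)))
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  phi <- wrap180(.rad2deg(theta - acs))
  alt <- wrap180(.rad2deg(theta + acs))
  use_alt <- (phi < -90 | phi > 90) & alt >= -90 & alt <= 90
  phi[use_alt] <- alt[use_alt]
  bad <- phi < -90 | phi > 90
  lat[solvable & !bad] <- phi[solvable & !bad]
  status[!solvable | bad] <- "unsolvable"
  degen <- abs(day_len - 12) < eps_hours
  status[degen] <- "indeterminate"
  lat[degen] <- NA_real_

  structure(
    data.frame(date = pairs$date, time = mid, type = pairs$type,
               lon = lon, lat = lat, lat_status = status,
               filters = "", retained = TRUE),
    class = c("geo_fixes", "data.frame"))
}

#' Calibrate the sun elevation angle of a device
#'
#' Grid search over candidate sun elevation angles: for each candidate, the
#' positions implied by the calibration-window twilights are computed and
#' scored by their median great-circle distance to the colony (the birds
#' are assumed to be colony-centred during late incubation/chick-rearing).
#' The angle with the smallest score wins; ties are broken by fewer on-land
#' points (when a coastline polygon is supplied) and then by proximity to
#' -3.5 degrees.
#'
#' @param pairs a [detect_twilights()] data.frame.
#' @param colony `c(lon, lat)` of the colony, degrees.
#' @param window `c(start, end)` `Date` vector delimiting the calibration
#'   period (`NULL` = all pairs).
#' @param grid candidate angles (degrees); default -5 to -2 by 0.25.
#' @param land_polygon optional two-column matrix (lon, lat) of a closed
#'   coastline polygon for the on-land tie-break.
#' @param min_pairs minimum usable twilight pairs required (default 10).
#' @return list of class `calibration_result`: `ea`, `score` (km),
#'   `n_on_land`, `window`, `table` (per-candidate scores).
#' @export
calibrate_ea <- function(pairs, colony, window = NULL,
                         grid = seq(-5, -2, by = 0.25),
                         land_polygon = NULL, min_pairs = 10) {
  if (length(grid) == 0) stop("empty EA grid")
  if (!is.null(window)) {
    pairs <- pairs[pairs$date >= window[1] & pairs$date <= window[2], , drop = FALSE]
  }
  if (sum(pairs$quality == "ok") < min_pairs) {
    stop("too few usable twilight pairs in the calibration window (",
         sum(pairs$quality == "ok"), " < ", min_pairs, ")")
  }
  score_one <- function(ea) {
    fx <- position_from_twilights(pairs, ea)
    ok <- !is.na(fx$lat)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    d <- .great_circle_km(fx$lon[ok], fx$lat[ok], colony[1], colony[2])
    n_land <- if (is.null(land_polygon)) 0L else
      sum(.point_in_polygon(fx$lon[ok], fx$lat[ok], land_polygon))
    c(stats::median(d), n_land)
  }
  sc <- vapply(grid, score_one, numeric(2))
  tab <- data.frame(ea = grid, score = sc[1, ], n_on_land = sc[2, ])
  if (all(is.na(tab$score))) stop("no usable (non-degenerate) fixes on the grid; all-equinox window?")
  o <- order(tab$score, tab$n_on_land, abs(tab$ea + 3.5))
  best <- tab[o[1], ]
  structure(list(ea = best$ea, score = best$score,
                 n_on_land = best$n_on_land, window = window, table = tab),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> EA = %.2f deg (median displacement %.1f km, %d on land)\n",
              x$ea, x$score, x$n_on_land))
  invisible(x)
}

# ray-casting point-in-polygon (lon/lat treated as planar; adequate for the
# coastline tie-break at regional scale)
.point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Filter a geolocation track
#'
#' Applies the filtering cascade to date-sorted fixes, flagging (never
#' deleting) fixes that fall in equinox windows (10 days on the winter
#' side and 5 days on the summer side of each equinox), fixes with
#' latitude outside `lat_bounds`, fixes with unusable latitude, and fixes
#' whose implied speed from the last retained fix exceeds `vmax` in a
#' single forward pass. `retained` is `TRUE` iff no flag applies.
#'
#' @param fixes a [position_from_twilights()] data.frame.
#' @param equinoxes `Date` vector of equinox dates; computed from the solar
#'   ephemeris for the years present when `NULL`.
#' @param vmax maximum plausible travel speed, km/h (default 55).
#' @param lat_bounds plausible latitude range (default `c(30, 52)`).
#' @param manual indices of fixes to flag manually (e.g. visually assessed
#'   interference).
#' @param method `"forward"` (single pass, default) or `"iterative"`
#'   (repeatedly drop the worst speed violator until none remain).
#' @return the fixes with `filters` (comma-joined flags from `equinox`,
#'   `lat_bounds`, `lat_missing`, `speed`, `manual`) and `retained`
#'   recomputed.
#' @export
filter_track <- function(fixes, equinoxes = NULL, vmax = 55,
                         lat_bounds = c(30, 52), manual = integer(0),
                         method = c("forward", "iterative")) {
  method <- match.arg(method)
  n <- nrow(fixes)
  if (n == 0) return(fixes)
  if (is.unsorted(fixes$date)) stop("fixes must be date-sorted")
  if (is.null(equinoxes)) {
    yrs <- unique(as.integer(format(fixes$date, "%Y")))
    equinoxes <- do.call(c, lapply(yrs, equinox_dates))
  }

  flags <- vector("list", n)
  for (i in seq_len(n)) flags[[i]] <- character(0)

  # equinox windows: winter side is toward the winter solstice
  for (eq in as.list(equinoxes)) {
    m <- as.integer(format(eq, "%m"))
    win <- if (m <= 6) c(eq - 10, eq + 5) else c(eq - 5, eq + 10)
    hit <- fixes$date >= win[1] & fixes$date <= win[2]
    for (i in which(hit)) flags[[i]] <- union(flags[[i]], "equinox")
  }
  miss <- is.na(fixes$lat)
  for (i in which(miss)) flags[[i]] <- union(flags[[i]], "lat_missing")
  outb <- !miss & (fixes$lat < lat_bounds[1] | fixes$lat > lat_bounds[2])
  for (i in which(outb)) flags[[i]] <- union(flags[[i]], "lat_bounds")
  for (i in intersect(manual, seq_len(n))) flags[[i]] <- union(flags[[i]], "manual")

  tm <- if ("time" %in% names(fixes)) as.numeric(fixes$time) else
    as.numeric(as.POSIXct(as.character(fixes$date), tz = "UTC")) + 43200

  speed_pass <- function(flags) {
    last <- NA_integer_
    for (i in seq_len(n)) {
      if (length(flags[[i]]) > 0) next
      if (!is.na(last)) {
        dt_h <- (tm[i] - tm[last]) / 3600
        if (dt_h > 0) {
          d_km <- .great_circle_km(fixes$lon[i], fixes$lat[i],
                                   fixes$lon[last], fixes$lat[last])
          if (d_km / dt_h > vmax) {
            flags[[i]] <- union(flags[[i]], "speed")
            next
          }
        }
      }
      last <- i
    }
    flags
  }
  if (method == "forward") {
    flags <- speed_pass(flags)
  } else {
    repeat {
      new_flags <- speed_pass(flags)
      if (identical(new_flags, flags)) break
      flags <- new_flags
    }
  }

  fixes$filters <- vapply(flags, paste, character(1), collapse = ",")
  fixes$retained <- fixes$filters == ""
  fixes
}
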