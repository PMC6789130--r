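# Independent brute-force oracles used across the suite. Each oracle
# recomputes a quantity by enumeration / direct formula evaluation, never
# through the code path it checks.

# day length (hours above the elevation `ea`) by dense-grid evaluation of
# the solar elevation on a 1-minute grid
oracle_day_length <- function(date, lon, lat, ea) {
  ts <- as.POSIXct(as.character(date), tz = "UTC") + seq(0, 86399, by = 60)
  up <- solar_elevation(ts, lon, lat) > ea
  sum(up) / 60
}

# closed-form day length: 2/15 * acos[(sin EA - sin phi sin delta) /
# (cos phi cos delta)] hours, declination taken at local noon
oracle_day_length_closed <- function(date, lon, lat, ea) {
  noon <- as.POSIXct(as.character(date), tz = "UTC") + (720 - 4 * lon) * 60
  decl <- solar_position(noon)$declination * pi / 180
  phi <- lat * pi / 180
  cosh0 <- (sin(ea * pi / 180) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  2 / 15 * acos(cosh0) * 180 / pi
}

# track-filter enumeration: independent loop over the cascade rules
oracle_filter <- function(fixes, equinoxes, vmax = 55, bounds = c(30, 52)) {
  n <- nrow(fixes)
  flagged <- rep(FALSE, n)
  for (eq in as.list(equinoxes)) {
    m <- as.integer(format(eq, "%m"))
    win <- if (m <= 6) c(eq - 10, eq + 5) else c(eq - 5, eq + 10)
    flagged <- flagged | (fixes$date >= win[1] & fixes$date <= win[2])
  }
  flagged <- flagged | is.na(fixes$lat) |
    (!is.na(fixes$lat) & (fixes$lat < bounds[1] | fixes$lat > bounds[2]))
  last <- NA
  for (i in seq_len(n)) {
    if (flagged[i]) next
    if (!is.na(last)) {
      dt <- as.numeric(fixes$time[i] - fixes$time[last], units = "hours")
      d <- geosphere::distHaversine(c(fixes$lon[i], fixes$lat[i]),
                                    c(fixes$lon[last], fixes$lat[last]),
                                    r = 6371.0088)
      if (d / dt > vmax) { flagged[i] <- TRUE; next }
    }
    last <- i
  }
  !flagged
}

# Ward agglomeration by Lance-Williams recursion on squared Euclidean
# distances (heights reported on the distance scale, as ward.D2)
oracle_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bmin <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bmin) { bmin <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bmin))
    merges[[step]] <- sort(unlist(members[c(i, j)]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# standard ellipse area by direct sums (no cov()/eigen() shortcuts beyond
# the quadratic formula for 2x2 eigenvalues)
oracle_sea <- function(d15N, d13C) {
  n <- length(d15N)
  mx <- sum(d15N) / n; my <- sum(d13C) / n
  sxx <- sum((d15N - mx)^2) / (n - 1)
  syy <- sum((d13C - my)^2) / (n - 1)
  sxy <- sum((d15N - mx) * (d13C - my)) / (n - 1)
  tr <- sxx + syy; det <- sxx * syy - sxy^2
  l1 <- (tr + sqrt(tr^2 - 4 * det)) / 2
  l2 <- (tr - sqrt(tr^2 - 4 * det)) / 2
  pi * sqrt(l1 * l2)
}

# one full phenology pass over a simulated bird
run_phenology <- function(s, light, immersion, ...) {
  nights <- night_intervals(s$days$date, s$colony[1], s$colony[2])
  daysiv <- day_intervals(s$days$date, s$colony[1], s$colony[2])
  nv <- detect_night_visits(immersion, nights)
  dv <- detect_day_visits(light, daysiv)
  phenology_summary(nv, dv, sex = s$sex, bird_id = s$bird_id, ...)
}

make_stationary <- function(seed, lon = 4, lat = 40) {
  s <- simulate_schedule("Menorca", 2012, seed = seed, sex = "M")
  s$days$lon <- lon; s$days$lat <- lat
  s$days$cave_day <- FALSE; s$days$colony_night <- FALSE
  s$days$transit <- FALSE
  s
}
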