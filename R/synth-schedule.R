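# Ground-truthed annual-cycle simulator for a burrow-nesting shearwater.
# The generator's defaults encode the study system: colonies attended
# roughly October-June, laying in early/mid March (latest on Menorca),
# ~51 d incubation shared in multi-day shifts, a female pre-laying exodus,
# and a Mediterranean-vs-Atlantic non-breeding choice per colony mixture.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer (or NULL)")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.sub_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * i) %% 2147483647)
}

#' Study colonies
#'
#' Locations and default migratory mixtures of the three study populations:
#' a Balearic shearwater colony on Mallorca, the hybrid-zone colony on
#' Menorca, and a Yelkouan shearwater colony in the Hyeres archipelago
#' (France). `p_atlantic` is the default probability that a bird from the
#' colony spends the non-breeding season in the Atlantic (the complement
#' covers the Mediterranean/Black Sea system).
#'
#' @return data.frame with columns `population`, `lon`, `lat`, `p_atlantic`,
#'   `laying_mean` (day of year).
#' @export
colony_table <- function() {
  data.frame(
    population = c("Mallorca", "Menorca", "Yelkouan"),
    lon = c(2.35, 4.32, 6.40),
    lat = c(39.60, 39.87, 43.00),
    p_atlantic = c(0.85, 0.20, 0.00),
    laying_mean = c(60, 77, 81),  # ~Mar 1, Mar 18, Mar 22
    stringsAsFactors = FALSE
  )
}

#' Default non-breeding region boxes
#'
#' Centroid-sampling boxes for the two destination systems; Black Sea
#' destinations are drawn as far-eastern Mediterranean-system centroids.
#'
#' @return named list of boxes, each `c(lon_min, lon_max, lat_min, lat_max)`.
#' @export
region_boxes <- function() {
  list(
    atlantic      = c(-12, -2, 38, 47),
    mediterranean = c(0, 10, 36, 43),
    black_sea     = c(28, 34, 41, 43)
  )
}

.great_circle_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

#' Simulate one bird-year behaviour schedule
#'
#' Generates a full-calendar-year schedule for one bird: daily positions, a
#' per-date state table (cave day / colony night / transit), and the
#' ground-truth annual-cycle event dates that the phenology module is meant
#' to recover. The bird attends its colony from January to a June/July
#' departure and again from an October return; it lays in spring, incubates
#' in alternating multi-day shifts with its (implicit) partner, and spends
#' July-September at a non-breeding centroid drawn from the colony's
#' Atlantic/Mediterranean mixture.
#'
#' Construction guarantees used by recovery tests: the bird's first cave day
#' is the laying date (males take the first incubation shift; females sit
#' through the day of laying), its last cave day is the hatch date, colony
#' night-visit gaps outside the female pre-laying exodus never exceed 4
#' nights, the exodus is the longest attendance-season absence, and daily
#' displacement never exceeds `max_step_km`.
#'
#' @param population `"Mallorca"`, `"Menorca"` or `"Yelkouan"`.
#' @param year calendar year simulated.
#' @param seed integer seed (optional; the current RNG stream is used when
#'   `NULL`).
#' @param sex `"M"` or `"F"`; drawn at random when `NULL`.
#' @param p_atlantic override of the colony's Atlantic probability.
#' @param bird_id identifier (auto-generated when `NULL`).
#' @param exodus_days length of the female pre-laying exodus (ignored for
#'   males); default drawn in 10-18 d.
#' @param max_step_km maximum daily displacement (default 600 km/day).
#' @return An object of class `behavior_schedule`: a list with elements
#'   `bird_id`, `population`, `sex`, `region`, `year`, `colony` (lon/lat),
#'   `laying_date`, `hatch_date`, `depart_date`, `return_date`, `days`
#'   (per-date data.frame: `date`, `lon`, `lat`, `cave_day`, `colony_night`,
#'   `transit`) and `truth` (the five phenology ground-truth dates).
#' @export
simulate_schedule <- function(population, year, seed = NULL, sex = NULL,
                              p_atlantic = NULL, bird_id = NULL,
                              exodus_days = NULL, max_step_km = 600) {
  cols <- colony_table()
  if (!population %in% cols$population) {
    stop("unknown population: ", population,
         " (expected one of ", paste(cols$population, collapse = ", "), ")")
  }
  info <- cols[cols$population == population, ]

  .with_seed(seed, {
    if (is.null(sex)) sex <- sample(c("M", "F"), 1)
    sex <- match.arg(sex, c("M", "F"))
    if (is.null(p_atlantic)) p_atlantic <- info$p_atlantic
    region <- if (stats::runif(1) < p_atlantic) "atlantic" else "mediterranean"
    if (is.null(bird_id)) {
      bird_id <- sprintf("%s_%d_%04d", substr(population, 1, 3), year,
                         sample.int(9999L, 1))
    }

    dates <- seq(as.Date(sprintf("%d-01-01", year)),
                 as.Date(sprintf("%d-12-31", year)), by = "day")
    origin <- dates[1]

    laying <- origin + round(info$laying_mean - 1 + stats::rnorm(1, 0, 5))
    hatch <- laying + 51
    depart <- hatch + round(stats::rnorm(1, 45, 5))
    return_d <- as.Date(sprintf("%d-10-05", year)) + round(stats::rnorm(1, 0, 6))
    if (return_d <= depart + 30) return_d <- depart + 31

    if (is.null(exodus_days)) exodus_days <- sample(10:18, 1)
    exodus_start <- laying - exodus_days

    ## --- incubation shifts -------------------------------------------------
    cave <- rep(FALSE, length(dates))
    names(cave) <- as.character(dates)
    bouts <- list()         # all shifts, tagged by owner
    t <- laying
    own_turn <- TRUE        # focal bird's partner role: first shift owner
    first_owner <- if (sex == "M") "self" else "partner"
    while (t <= hatch) {
      len <- sample(3:5, 1)
      end <- min(t + len - 1, hatch)
      owner <- if (own_turn) first_owner else
        if (first_owner == "self") "partner" else "self"
      bouts[[length(bouts) + 1]] <- list(start = t, end = end, owner = owner)
      t <- end + 1
      own_turn <- !own_turn
    }
    own_days <- as.Date(character(0))
    for (b in bouts) if (b$owner == "self") {
      own_days <- c(own_days, seq(b$start, b$end, by = "day"))
    }
    if (sex == "F") own_days <- c(laying, own_days)   # sits through laying day
    own_days <- unique(c(own_days, hatch))            # brooding day at hatch
    cave[as.character(own_days)] <- TRUE

    ## --- colony nights -----------------------------------------------------
    night <- rep(FALSE, length(dates))
    names(night) <- as.character(dates)
    visit_seq <- function(from, to) {
      out <- as.Date(character(0))
      d <- from
      while (d <= to) {
        out <- c(out, d)
        d <- d + sample(1:4, 1)
      }
      out
    }
    # pre-laying attendance (interrupted by the female exodus)
    pre <- visit_seq(origin, laying - 1)
    if (sex == "F") pre <- pre[pre < exodus_start]
    night[as.character(pre)] <- TRUE
    # incubation: nights of own shift days only
    night[as.character(own_days[own_days >= laying & own_days <= hatch])] <- TRUE
    if (sex == "F") night[as.character(laying)] <- TRUE
    # chick rearing up to departure; guarantee a visit on the departure night
    cr <- visit_seq(hatch + 1, depart - 1)
    night[as.character(cr)] <- TRUE
    night[as.character(depart)] <- TRUE
    # post-return attendance
    post <- visit_seq(return_d, dates[length(dates)])
    night[as.character(post)] <- TRUE
    night[as.character(return_d)] <- TRUE
    night[names(night) > as.character(depart) &
            names(night) < as.character(return_d)] <- FALSE
    if (sex == "F") {
      ex_days <- seq(exodus_start, laying - 1, by = "day")
      night[as.character(ex_days)] <- FALSE
      cave[as.character(ex_days)] <- FALSE
    }

    ## --- daily positions ---------------------------------------------------
    box <- if (region == "atlantic") {
      region_boxes()$atlantic
    } else if (population == "Yelkouan" && stats::runif(1) < 0.3) {
      region_boxes()$black_sea
    } else {
      region_boxes()$mediterranean
    }
    centroid <- c(stats::runif(1, box[1], box[2]), stats::runif(1, box[3], box[4]))

    lon <- rep(info$lon, length(dates))
    lat <- rep(info$lat, length(dates))
    transit <- rep(FALSE, length(dates))
    home <- dates <= depart | dates >= return_d
    # near-colony foraging scatter on home days
    lon[home] <- info$lon + stats::runif(sum(home), -0.3, 0.3)
    lat[home] <- info$lat + stats::runif(sum(home), -0.3, 0.3)
    lon[cave | night] <- info$lon
    lat[cave | night] <- info$lat

    gc_km <- .great_circle_km(info$lon, info$lat, centroid[1], centroid[2])
    n_leg <- max(1, ceiling(gc_km / (0.75 * max_step_km)))
    away <- which(dates > depart & dates < return_d)
    if (length(away) > 2 * n_leg + 2) {
      out_leg <- away[seq_len(n_leg)]
      back_leg <- away[seq(length(away) - n_leg + 1, length(away))]
      frac_out <- seq_along(out_leg) / n_leg
      lon[out_leg] <- info$lon + frac_out * (centroid[1] - info$lon)
      lat[out_leg] <- info$lat + frac_out * (centroid[2] - info$lat)
      frac_back <- rev(seq_along(back_leg) - 1) / n_leg
      lon[back_leg] <- info$lon + frac_back * (centroid[1] - info$lon)
      lat[back_leg] <- info$lat + frac_back * (centroid[2] - info$lat)
      transit[c(out_leg, back_leg)] <- TRUE
      resident <- setdiff(away, c(out_leg, back_leg))
      # mean-reverting wander around the centroid (stationary SD ~ 0.5 deg)
      ar1 <- function(n, sd) {
        e <- stats::rnorm(n, 0, sd); o <- numeric(n); prev <- 0
        for (t in seq_len(n)) { prev <- 0.85 * prev + e[t]; o[t] <- prev }
        o
      }
      lon[resident] <- centroid[1] + ar1(length(resident), 0.25)
      lat[resident] <- centroid[2] + ar1(length(resident), 0.18)
    } else {
      lon[away] <- centroid[1]
      lat[away] <- centroid[2]
    }

    days <- data.frame(
      date = dates, lon = lon, lat = lat,
      cave_day = unname(cave), colony_night = unname(night),
      transit = transit
    )

    structure(list(
      bird_id = bird_id, population = population, sex = sex, region = region,
      year = year, colony = c(lon = info$lon, lat = info$lat),
      laying_date = laying, hatch_date = hatch,
      depart_date = depart, return_date = return_d,
      nb_centroid = c(lon = centroid[1], lat = centroid[2]),
      days = days,
      truth = list(
        last_night_visit = depart, first_night_visit = return_d,
        first_day_visit = laying, laying_date = laying,
        last_day_visit = hatch
      )
    ), class = "behavior_schedule")
  })
}

#' Simulate a cohort of bird-years
#'
#' @inheritParams simulate_schedule
#' @param n number of birds.
#' @return list of `behavior_schedule` objects.
#' @export
simulate_cohort <- function(population, year, n, seed = NULL, ...) {
  lapply(seq_len(n), function(i) {
    simulate_schedule(population, year, seed = .sub_seed(seed, i),
                      bird_id = sprintf("%s_%d_%04d", substr(population, 1, 3),
                                        year, i), ...)
  })
}

#' @export
print.behavior_schedule <- function(x, ...) {
  cat(sprintf(
    "<behavior_schedule> %s (%s, %s) %d\n  region: %s | laying %s | hatch %s | depart %s | return %s\n",
    x$bird_id, x$population, x$sex, x$year, x$region,
    format(x$laying_date), format(x$hatch_date),
    format(x$depart_date), format(x$return_date)
  ))
  invisible(x)
}
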