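# Forward model of a salt-water immersion (wet/dry) logger: integer wet
# counts per sampling block, driven by the behavioural state timeline.

#' Simulate a salt-water immersion series from a behaviour schedule
#'
#' Each block of `block` minutes receives an integer wet count in
#' `[0, samples_per_block]`:
#' \itemize{
#'   \item in-cave periods (incubation days, and colony-attendance nights
#'     from half an hour after dusk to half an hour before dawn) are
#'     completely dry (wet count 0);
#'   \item at-sea nights are spent rafting on the water: wet counts of at
#'     least `0.85 * samples_per_block`, never zero, so at-sea nights can
#'     never imitate a colony visit;
#'   \item at-sea foraging days have intermediate stochastic wet counts;
#'   \item transit (sustained flight) days are mostly dry by day but still
#'     wet at night (birds sit on the water).
#' }
#' Night here means sun below -6 degrees at the bird's position.
#'
#' @param schedule a [simulate_schedule()] object.
#' @param block block length in minutes (default 10).
#' @param samples_per_block wet/dry samples summarised per block
#'   (default 200, i.e. one sample every 3 s).
#' @param seed integer seed (optional).
#' @return A data.frame of class `immersion_series` with columns
#'   `timestamp` (block start, `POSIXct` UTC) and `wet_count`, and
#'   attributes `bird_id`, `block`, `samples_per_block`.
#' @export
simulate_immersion <- function(schedule, block = 10, samples_per_block = 200,
                               seed = NULL) {
  stopifnot(inherits(schedule, "behavior_schedule"))
  days <- schedule$days
  if (any(diff(days$date) != 1)) stop("schedule has gaps")

  .with_seed(seed, {
    t0 <- as.POSIXct(as.character(days$date[1]), tz = "UTC")
    t1 <- as.POSIXct(as.character(days$date[nrow(days)]), tz = "UTC") + 86400 - block * 60
    ts <- seq(t0, t1, by = block * 60)
    n <- length(ts)
    day_idx <- findInterval(as.numeric(ts),
                            as.numeric(as.POSIXct(as.character(days$date), tz = "UTC")))

    # night window (sun < -6 deg) at the bird's position, per date
    tw <- night_intervals(days$date, days$lon, days$lat, ea = -6)
    # block is "night of date d" if inside [dusk_d, dawn_(d+1)); a block in
    # the early hours belongs to the previous date's night
    dusk_prev <- c(as.POSIXct(NA), tw$dusk[-nrow(tw)])
    dawn_this <- c(as.POSIXct(NA), tw$dawn[-nrow(tw)])
    t_num <- as.numeric(ts)
    in_night_of_own <- t_num >= as.numeric(tw$dusk[day_idx])
    in_night_of_prev <- t_num < as.numeric(dawn_this[day_idx])
    in_night_of_own[is.na(in_night_of_own)] <- FALSE
    in_night_of_prev[is.na(in_night_of_prev)] <- FALSE
    is_night <- in_night_of_own | in_night_of_prev
    night_date_idx <- ifelse(in_night_of_own, day_idx, day_idx - 1)
    night_date_idx[night_date_idx < 1] <- 1

    colony_night <- days$colony_night[night_date_idx] & is_night
    # in-cave core of the attendance night: dusk + 30 min to dawn - 30 min
    core <- rep(FALSE, n)
    core[in_night_of_own] <-
      t_num[in_night_of_own] >= as.numeric(tw$dusk[day_idx[in_night_of_own]]) + 1800
    core[in_night_of_prev] <-
      t_num[in_night_of_prev] <= as.numeric(dawn_this[day_idx[in_night_of_prev]]) - 1800
    in_cave_night <- colony_night & core

    cave_day <- days$cave_day[day_idx] & !is_night
    # incubating birds are also in the cave through their shift nights
    in_cave <- in_cave_night | cave_day |
      (days$cave_day[night_date_idx] & is_night & days$colony_night[night_date_idx])

    transit <- days$transit[day_idx]

    wet <- integer(n)
    at_sea_night <- is_night & !in_cave & !colony_night
    # rafting: high wet counts, never zero
    k <- sum(at_sea_night)
    wet[at_sea_night] <- pmax(1L, as.integer(round(
      stats::runif(k, 0.85, 1) * samples_per_block)))
    # colony-attendance night but outside the cave core: rafting offshore
    pre_post <- colony_night & !in_cave
    wet[pre_post] <- pmax(1L, as.integer(round(
      stats::runif(sum(pre_post), 0.85, 1) * samples_per_block)))

    at_sea_day <- !is_night & !in_cave
    forage <- at_sea_day & !transit
    p_forage <- stats::runif(sum(forage), 0.15, 0.6)
    wet[forage] <- stats::rbinom(sum(forage), samples_per_block, p_forage)
    fly <- at_sea_day & transit
    wet[fly] <- stats::rbinom(sum(fly), samples_per_block, 0.04)

    wet[in_cave] <- 0L

    structure(
      data.frame(timestamp = ts, wet_count = wet),
      class = c("immersion_series", "data.frame"),
      bird_id = schedule$bird_id, block = block,
      samples_per_block = samples_per_block
    )
  })
}
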