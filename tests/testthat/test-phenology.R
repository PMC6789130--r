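# helpers to construct miniature immersion/light traces with known patterns
mk_blocks <- function(date, block_min = 10) {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  seq(t0, t0 + 86400 * 2 - block_min * 60, by = block_min * 60)
}

test_that("night visits require 2 h of continuous dryness", {
  ts <- mk_blocks("2012-03-01")
  nights <- data.frame(date = as.Date("2012-03-01"),
                       dusk = as.POSIXct("2012-03-01 18:00", tz = "UTC"),
                       dawn = as.POSIXct("2012-03-02 05:30", tz = "UTC"))
  wet <- rep(150L, length(ts))
  # 7 h of dryness 22:00-05:00
  dry <- ts >= as.POSIXct("2012-03-01 22:00", tz = "UTC") &
    ts < as.POSIXct("2012-03-02 05:00", tz = "UTC")
  wet[dry] <- 0L
  ev <- detect_night_visits(data.frame(timestamp = ts, wet_count = wet), nights)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$date, as.Date("2012-03-01"))
  # alternating wet/dry blocks all night: no visit
  wet2 <- rep(c(0L, 100L), length.out = length(ts))
  ev2 <- detect_night_visits(data.frame(timestamp = ts, wet_count = wet2), nights)
  expect_equal(nrow(ev2), 0)
  # all-night rafting: longest dry run < 2 h
  wet3 <- rep(180L, length(ts))
  ev3 <- detect_night_visits(data.frame(timestamp = ts, wet_count = wet3), nights)
  expect_equal(nrow(ev3), 0)
})

test_that("the dry-run threshold rescales with block length", {
  # same underlying wet pattern at 10-min and 5-min resolution
  for (block in c(10, 5)) {
    ts <- mk_blocks("2012-03-01", block)
    nights <- data.frame(date = as.Date("2012-03-01"),
                         dusk = as.POSIXct("2012-03-01 18:00", tz = "UTC"),
                         dawn = as.POSIXct("2012-03-02 06:00", tz = "UTC"))
    wet <- rep(100L, length(ts))
    dry <- ts >= as.POSIXct("2012-03-01 23:00", tz = "UTC") &
      ts < as.POSIXct("2012-03-02 02:00", tz = "UTC")
    wet[dry] <- 0L
    ev <- detect_night_visits(data.frame(timestamp = ts, wet_count = wet), nights)
    expect_equal(nrow(ev), 1)
    # 1.5 h of dryness never qualifies, at either resolution
    wet[] <- 100L
    dry2 <- ts >= as.POSIXct("2012-03-01 23:00", tz = "UTC") &
      ts < as.POSIXct("2012-03-02 00:30", tz = "UTC")
    wet[dry2] <- 0L
    ev2 <- detect_night_visits(data.frame(timestamp = ts, wet_count = wet), nights)
    expect_equal(nrow(ev2), 0)
  }
})

test_that("day visits require complete daytime darkness", {
  ts <- seq(as.POSIXct("2012-03-01 00:00", tz = "UTC"), by = 600,
            length.out = 144)
  days <- data.frame(date = as.Date("2012-03-01"),
                     dawn = as.POSIXct("2012-03-01 06:30", tz = "UTC"),
                     dusk = as.POSIXct("2012-03-01 17:30", tz = "UTC"))
  light <- rep(0, length(ts))
  ev <- detect_day_visits(data.frame(timestamp = ts, light = light), days)
  expect_equal(nrow(ev), 1)
  light[ts == as.POSIXct("2012-03-01 12:00", tz = "UTC")] <- 64
  ev2 <- detect_day_visits(data.frame(timestamp = ts, light = light), days)
  expect_equal(nrow(ev2), 0)
  # missing daytime samples are skipped with a warning
  days2 <- rbind(days, data.frame(date = as.Date("2012-03-02"),
                                  dawn = as.POSIXct("2012-03-02 06:30", tz = "UTC"),
                                  dusk = as.POSIXct("2012-03-02 17:30", tz = "UTC")))
  expect_warning(detect_day_visits(data.frame(timestamp = ts, light = 0), days2),
                 "skipped")
})

test_that("non-breeding bounds pick the unique longest absence", {
  v <- data.frame(date = c(seq(as.Date("2012-05-01"), as.Date("2012-06-10"), 1),
                           seq(as.Date("2012-10-02"), as.Date("2012-11-01"), 2)))
  nb <- nonbreeding_bounds(v)
  expect_equal(nb$start, as.Date("2012-06-10"))
  expect_equal(nb$end, as.Date("2012-10-02"))
  # no long gap
  expect_error(nonbreeding_bounds(data.frame(date = as.Date("2012-05-01") + 0:40)),
               "no non-breeding period")
  # two equal maximal gaps: ambiguous by contract
  tied <- data.frame(date = as.Date("2012-01-01") + c(0, 50, 100))
  expect_error(nonbreeding_bounds(tied), "ambiguous")
})

test_that("laying rules follow sex-specific attendance patterns", {
  # male: first >= 2-day day-visit run; a 1-day run does not count
  dv <- data.frame(date = as.Date(c("2012-03-10", "2012-03-20", "2012-03-21",
                                    "2012-03-22")), kind = "day_visit")
  nv <- data.frame(date = as.Date("2012-02-01") + 0:50, kind = "night_visit")
  expect_equal(infer_laying_date(dv, nv, "M"), as.Date("2012-03-20"))
  # no qualifying run
  solo <- dv[1, , drop = FALSE]
  expect_true(is.na(infer_laying_date(solo, nv, "M")))
  # female: first visit after a 12-day absence ending Mar 18
  nvf <- data.frame(date = c(as.Date("2012-02-01") + 0:33,
                             as.Date("2012-03-18") + 0:5))
  dvf <- data.frame(date = as.Date("2012-03-18") + 0:5)
  expect_equal(infer_laying_date(dvf, nvf, "F"), as.Date("2012-03-18"))
})

test_that("pair rule finds the first alternating incubation pattern", {
  own <- data.frame(date = c(as.Date("2012-03-18"),
                             as.Date("2012-03-22") + 0:2,
                             as.Date("2012-03-29") + 0:2))
  partner <- data.frame(date = c(as.Date("2012-03-18") + 0:3,
                                 as.Date("2012-03-25") + 0:3))
  lay <- infer_laying_date(own, data.frame(date = as.Date("2012-02-01") + 0:45),
                           sex = "F", partner_day_visits = partner)
  expect_equal(lay, as.Date("2012-03-18"))
})

test_that("return-date imputation takes the cohort median (earlier on ties)", {
  mk <- function(d) data.frame(bird_id = "x", sex = "M",
                               last_night_visit = as.Date("2012-06-01"),
                               first_night_visit = as.Date(d),
                               first_day_visit = as.Date(NA),
                               laying_date = as.Date(NA),
                               last_day_visit = as.Date(NA), imputed = "")
  cohort <- do.call(rbind, lapply(c("2012-10-02", "2012-10-06", "2012-10-20"), mk))
  target <- mk(NA)
  out <- impute_return_date(cohort, target)
  expect_equal(out$first_night_visit, as.Date("2012-10-06"))
  expect_match(out$imputed, "first_night_visit")
  # even cohort: earlier of the two central dates
  cohort4 <- do.call(rbind, lapply(c("2012-10-02", "2012-10-06",
                                     "2012-10-10", "2012-10-20"), mk))
  expect_equal(impute_return_date(cohort4, target)$first_night_visit,
               as.Date("2012-10-06"))
  # identical dates return that date; small cohorts warn
  same <- do.call(rbind, lapply(rep("2012-10-07", 3), mk))
  expect_equal(impute_return_date(same, target)$first_night_visit,
               as.Date("2012-10-07"))
  expect_warning(impute_return_date(cohort[1:2, ], target), "fewer than")
})

test_that("all five phenology dates are recovered exactly on noiseless birds", {
  for (i in 1:6) {
    sx <- if (i %% 2 == 0) "M" else "F"
    s <- simulate_schedule("Menorca", 2012, seed = 400 + i, sex = sx)
    li <- simulate_light(s, cadence = 10, seed = 500 + i)
    im <- simulate_immersion(s, seed = 600 + i)
    ps <- run_phenology(s, li, im)
    expect_equal(ps$last_night_visit, s$truth$last_night_visit)
    expect_equal(ps$first_night_visit, s$truth$first_night_visit)
    expect_equal(ps$first_day_visit, s$truth$first_day_visit)
    expect_equal(ps$laying_date, s$truth$laying_date)
    expect_equal(ps$last_day_visit, s$truth$last_day_visit)
    # ordering invariant
    expect_true(ps$first_day_visit <= ps$laying_date)
    expect_true(ps$laying_date <= ps$last_day_visit)
  }
})

test_that("immersion-driven events are unchanged by twilight jitter", {
  s <- simulate_schedule("Mallorca", 2012, seed = 77, sex = "M")
  im <- simulate_immersion(s, seed = 78)
  nights <- night_intervals(s$days$date, s$colony[1], s$colony[2])
  nv <- detect_night_visits(im, nights)
  nb <- nonbreeding_bounds(nv)
  expect_equal(nb$start, s$truth$last_night_visit)
  expect_equal(nb$end, s$truth$first_night_visit)
  # light jitter cannot touch these events (they are immersion-only), and
  # cave-day detection is jitter-robust because cave days are fully dark
  li <- simulate_light(s, cadence = 10, jitter_sd = 4, seed = 79)
  daysiv <- day_intervals(s$days$date, s$colony[1], s$colony[2])
  dv <- detect_day_visits(li, daysiv)
  lay <- infer_laying_date(dv, nv, sex = "M")
  expect_lte(abs(as.numeric(lay - s$truth$laying_date)), 1)
})
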