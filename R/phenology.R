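# Colony-attendance phenology from immersion and light traces: night
# visits (continuous night-time dryness >= 2 h), cave day visits (complete
# daytime darkness), non-breeding bounds, laying-date rules, and median
# imputation of missing returns.

.runs_of_dates <- function(dates) {
  if (length(dates) == 0) return(data.frame(start = as.Date(character(0)),
                                            end = as.Date(character(0)),
                                            length = integer(0)))
  dates <- sort(unique(dates))
  brk <- c(0, which(diff(dates) != 1), length(dates))
  data.frame(
    start = dates[head(brk, -1) + 1],
    end = dates[brk[-1]],
    length = as.integer(diff(brk))
  )
}

#' Detect colony night visits from an immersion trace
#'
#' A night yields a night visit iff it contains a run of completely dry
#' blocks (wet count 0) of at least `min_dry_hours` (2 h by default; the
#' run-length threshold is rescaled to the series' actual block length, so
#' e.g. 10-min blocks require >= 12 consecutive dry blocks).
#'
#' @param immersion data.frame with `timestamp`, `wet_count` (e.g. from
#'   [simulate_immersion()] or [read_immersion_csv()]).
#' @param nights data.frame with `date`, `dusk`, `dawn` (e.g. from
#'   [night_intervals()]); the night labelled d runs from dusk of d to dawn
#'   of d+1.
#' @param min_dry_hours minimum continuous dryness (default 2).
#' @return data.frame with columns `date`, `kind` (`"night_visit"`),
#'   `start`, `end` (bounds of the qualifying dry run).
#' @export
detect_night_visits <- function(immersion, nights, min_dry_hours = 2) {
  block_min <- stats::median(diff(as.numeric(immersion$timestamp))) / 60
  need <- ceiling(min_dry_hours * 60 / block_min)
  tnum <- as.numeric(immersion$timestamp)
  out <- list()
  for (i in seq_len(nrow(nights))) {
    sel <- tnum >= as.numeric(nights$dusk[i]) & tnum < as.numeric(nights$dawn[i])
    if (!any(sel)) next
    wet <- immersion$wet_count[sel]
    tt <- tnum[sel]
    r <- rle(wet == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= need)
    if (length(hit)) {
      j <- hit[1]
      out[[length(out) + 1]] <- data.frame(
        date = nights$date[i], kind = "night_visit",
        start = as.POSIXct(tt[starts[j]], origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(tt[ends[j]] + block_min * 60,
                         origin = "1970-01-01", tz = "UTC")
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(date = as.Date(character(0)), kind = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect colony (cave) day visits from a light trace
#'
#' A date yields a day visit iff every daytime light sample is below the
#' threshold: birds incubating inside a nesting cave record complete
#' daytime darkness.
#'
#' @param light data.frame with `timestamp`, `light`.
#' @param days data.frame with `date`, `dawn`, `dusk` (e.g. from
#'   [day_intervals()]).
#' @param threshold light threshold (default 10).
#' @return data.frame with columns `date`, `kind` (`"day_visit"`), `start`,
#'   `end` (the daylight interval). Dates without daytime samples are
#'   skipped with a warning.
#' @export
detect_day_visits <- function(light, days, threshold = 10) {
  tnum <- as.numeric(light$timestamp)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(days))) {
    sel <- tnum >= as.numeric(days$dawn[i]) & tnum <= as.numeric(days$dusk[i])
    if (!any(sel)) { skipped <- skipped + 1L; next }
    if (all(light$light[sel] < threshold)) {
      out[[length(out) + 1]] <- data.frame(
        date = days$date[i], kind = "day_visit",
        start = days$dawn[i], end = days$dusk[i]
      )
    }
  }
  if (skipped > 0) warning(skipped, " date(s) without daytime samples skipped")
  if (length(out) == 0) {
    return(data.frame(date = as.Date(character(0)), kind = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Non-breeding period bounds from night visits
#'
#' The non-breeding period starts at the last night visit before the
#' longest gap between consecutive night visits and ends at the first
#' night visit after it (departure for, and return from, migration).
#'
#' @param night_visits a [detect_night_visits()] data.frame (or any
#'   data.frame with a `date` column).
#' @param min_migration_days the longest gap must exceed this many absent
#'   days to count as a migration (default 30); guards against mid-season
#'   absences.
#' @return list with `start` and `end` (`Date`).
#' @export
nonbreeding_bounds <- function(night_visits, min_migration_days = 30) {
  d <- sort(unique(night_visits$date))
  if (length(d) < 2) stop("no non-breeding period detected: fewer than two night visits")
  gaps <- as.numeric(diff(d)) - 1
  mx <- max(gaps)
  if (mx <= min_migration_days) {
    stop("no non-breeding period detected: longest absence (", mx,
         " d) does not exceed min_migration_days (", min_migration_days, ")")
  }
  if (sum(gaps == mx) > 1) {
    stop("ambiguous non-breeding period: two equally long absences of ", mx, " days")
  }
  i <- which.max(gaps)
  list(start = d[i], end = d[i + 1])
}

#' Infer the laying date from attendance patterns
#'
#' Sex-specific rules:
#' \itemize{
#'   \item males: the first day of the first run of day visits lasting at
#'     least 2 days (the male takes the first long incubation shift);
#'   \item females: the first colony visit (night or day) after the longest
#'     at-sea absence exceeding `exodus_min_days` (the pre-laying exodus);
#'   \item pairs (when `partner_day_visits` is supplied): the start of the
#'     first alternating incubation pattern -- two successive day-visit
#'     runs belonging to different pair members, non-overlapping and
#'     abutting -- falling back to the single-bird sex rule if no such
#'     pattern exists.
#' }
#'
#' @param day_visits,night_visits event data.frames for the focal bird.
#' @param sex `"M"` or `"F"`.
#' @param partner_day_visits optional day-visit events of the partner.
#' @param exodus_min_days minimum absence (absent days) to qualify as the
#'   pre-laying exodus (default 5).
#' @param search_end latest date considered when locating the exodus
#'   (default: the focal bird's last day visit, so the post-breeding
#'   migration gap is never mistaken for an exodus).
#' @return a `Date`, or `NA` with a `reason` attribute when no qualifying
#'   pattern exists.
#' @export
infer_laying_date <- function(day_visits, night_visits, sex,
                              partner_day_visits = NULL,
                              exodus_min_days = 5, search_end = NULL) {
  sex <- match.arg(sex, c("M", "F"))

  if (!is.null(partner_day_visits)) {
    own <- .runs_of_dates(day_visits$date)
    oth <- .runs_of_dates(partner_day_visits$date)
    if (nrow(own) && nrow(oth)) {
      own$owner <- "self"; oth$owner <- "partner"
      runs <- rbind(own, oth)
      runs <- runs[order(runs$start, runs$end), ]
      if (nrow(runs) >= 2) {
        for (i in seq_len(nrow(runs) - 1)) {
          if (runs$owner[i] != runs$owner[i + 1] &&
              runs$start[i + 1] == runs$end[i] + 1) {
            return(runs$start[i])
          }
        }
      }
    }
    # no alternating pattern: fall through to the sex rule
  }

  if (sex == "M") {
    runs <- .runs_of_dates(day_visits$date)
    ok <- runs[runs$length >= 2, , drop = FALSE]
    if (nrow(ok) == 0) {
      return(structure(as.Date(NA), reason = "no day-visit run of >= 2 days"))
    }
    return(ok$start[1])
  }

  visits <- sort(unique(c(day_visits$date, night_visits$date)))
  if (is.null(search_end)) {
    search_end <- if (nrow(day_visits)) max(day_visits$date) else max(visits)
  }
  visits <- visits[visits <= search_end]
  if (length(visits) < 2) {
    return(structure(as.Date(NA), reason = "too few visits to locate an exodus"))
  }
  gaps <- as.numeric(diff(visits)) - 1
  mx <- max(gaps)
  if (mx <= exodus_min_days) {
    return(structure(as.Date(NA), reason = "no absence exceeding exodus_min_days"))
  }
  visits[which.max(gaps) + 1]
}

#' Per-bird phenology summary
#'
#' Combines the event detectors into the five annual-cycle dates: last and
#' first night visit (non-breeding start/end), first day visit, laying date
#' and last day visit (hatching proxy).
#'
#' @param night_visits,day_visits event data.frames.
#' @param sex `"M"` or `"F"`.
#' @param bird_id identifier carried into the output.
#' @param ... passed to [infer_laying_date()] and [nonbreeding_bounds()].
#' @param min_migration_days see [nonbreeding_bounds()].
#' @return one-row data.frame of class `phenology_summary` with the five
#'   dates and an `imputed` column (comma-joined names of imputed fields,
#'   empty here; see [impute_return_date()]).
#' @export
phenology_summary <- function(night_visits, day_visits, sex, bird_id = NA,
                              min_migration_days = 30, ...) {
  nb <- tryCatch(nonbreeding_bounds(night_visits, min_migration_days),
                 error = function(e) list(start = as.Date(NA), end = as.Date(NA)))
  laying <- infer_laying_date(day_visits, night_visits, sex, ...)
  first_dv <- if (nrow(day_visits)) min(day_visits$date) else as.Date(NA)
  last_dv <- if (nrow(day_visits)) max(day_visits$date) else as.Date(NA)
  structure(
    data.frame(bird_id = bird_id, sex = sex,
               last_night_visit = nb$start, first_night_visit = nb$end,
               first_day_visit = first_dv, laying_date = as.Date(laying),
               last_day_visit = last_dv, imputed = "",
               stringsAsFactors = FALSE),
    class = c("phenology_summary", "data.frame"))
}

#' Impute a missing return date from the colony-year cohort
#'
#' For a bird whose logger failed before its return, the first night visit
#' is imputed as the cohort median of observed first night visits
#' (day-of-year arithmetic; with an even cohort the earlier of the two
#' central dates is used, for determinism).
#'
#' @param cohort a data.frame of phenology summaries (rows = birds of the
#'   same colony-year) with a `first_night_visit` column.
#' @param target one-row phenology summary to fill.
#' @param min_cohort minimum observed returns required (default 3).
#' @return `target` with `first_night_visit` set and `"first_night_visit"`
#'   appended to its `imputed` field; unchanged (with a warning) when the
#'   cohort is too small.
#' @export
impute_return_date <- function(cohort, target, min_cohort = 3) {
  obs <- cohort$first_night_visit
  obs <- obs[!is.na(obs)]
  if ("imputed" %in% names(cohort)) {
    keep <- !grepl("first_night_visit", cohort$imputed) | is.na(cohort$first_night_visit)
    obs <- cohort$first_night_visit[keep & !is.na(cohort$first_night_visit)]
  }
  if (length(obs) < min_cohort) {
    warning("cohort has fewer than ", min_cohort,
            " observed returns; nothing imputed")
    return(target)
  }
  obs <- sort(obs)
  med <- obs[ceiling(length(obs) / 2)]  # even n: earlier central value
  target$first_night_visit <- med
  target$imputed <- if (nzchar(target$imputed)) {
    paste(target$imputed, "first_night_visit", sep = ",")
  } else "first_night_visit"
  target
}
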