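# End-to-end orchestration: simulate -> geolocate -> phenology -> kde ->
# isotope assignment, with a JSON config, derived per-stage seeds, and a
# run manifest. All interchange is plain CSV/JSON so any stage can be
# replaced by external data in the same layout.

#' Build a pipeline configuration
#'
#' @param seed master seed; every stochastic stage receives a sub-seed
#'   derived from it.
#' @param out_dir output directory.
#' @param populations colonies simulated (subset of
#'   `colony_table()$population`).
#' @param n_birds birds per colony.
#' @param year simulated year.
#' @param threshold light threshold.
#' @param ea_true device sun elevation angle used by the simulator.
#' @param ea_grid calibration grid.
#' @param jitter_sd twilight jitter SD (minutes).
#' @param cadence light sampling cadence (minutes).
#' @param vmax speed-filter limit (km/h).
#' @param exodus_min_days female laying rule parameter.
#' @param kde_levels contour levels (percent).
#' @param cell_km KDE cell size (km; population-scale maps need coarser
#'   cells than the 1-km individual cores).
#' @param n_untracked untracked birds per colony for isotope assignment.
#' @param classifier `"fit"` (train on the simulated tracked birds) or a
#'   preset name (`"p6"`, `"p1"`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            populations = c("Mallorca", "Menorca"),
                            n_birds = 2, year = 2012, threshold = 10,
                            ea_true = -3.5, ea_grid = seq(-5, -2, 0.25),
                            jitter_sd = 0, cadence = 10, vmax = 55,
                            exodus_min_days = 5,
                            kde_levels = c(25, 50, 70, 90), cell_km = 10,
                            n_untracked = 5, classifier = "fit") {
  cfg <- list(seed = seed, out_dir = out_dir, populations = populations,
              n_birds = n_birds, year = year, threshold = threshold,
              ea_true = ea_true, ea_grid = ea_grid, jitter_sd = jitter_sd,
              cadence = cadence, vmax = vmax,
              exodus_min_days = exodus_min_days, kde_levels = kde_levels,
              cell_km = cell_km, n_untracked = n_untracked,
              classifier = classifier)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path.
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config validation: `seed` is required")
  if (is.null(cfg$out_dir)) stop("config validation: `out_dir` is required")
  known <- colony_table()
  bad <- setdiff(cfg$populations, known$population)
  if (length(bad)) stop("config validation: unknown population(s) ",
                        paste(bad, collapse = ", "))
  ct <- known[match(cfg$populations, known$population), ]
  if (anyNA(ct$lon) || anyNA(ct$lat)) {
    stop("config validation: colony lon/lat missing")
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes simulate, geolocate, phenology, kde and isotope-assignment
#' stages in order, writing every interface file under `cfg$out_dir` and a
#' manifest JSON (package version, seeds, per-stage record counts, output
#' file hashes). A stage failure aborts with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param cfg a [pipeline_config()] object.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  .validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("puffintrack")),
    r_version = R.version.string,
    seed = cfg$seed, stages = list(), files = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  ## -- simulate ------------------------------------------------------------
  birds <- list(); untracked <- list()
  stage("simulate", {
    k <- 0
    for (popn in cfg$populations) {
      cohort <- simulate_cohort(popn, cfg$year, cfg$n_birds,
                                seed = .sub_seed(cfg$seed, 1000 + k))
      for (b in cohort) {
        li <- simulate_light(b, ea_true = cfg$ea_true,
                             jitter_sd = cfg$jitter_sd,
                             cadence = cfg$cadence,
                             seed = .sub_seed(cfg$seed, 2000 + length(birds)))
        im <- simulate_immersion(b, seed = .sub_seed(cfg$seed, 3000 + length(birds)))
        write_light_csv(li, out(paste0(b$bird_id, "_light.csv")))
        write_immersion_csv(im, out(paste0(b$bird_id, "_immersion.csv")))
        birds[[b$bird_id]] <- list(schedule = b, light = li, immersion = im)
      }
      un <- simulate_cohort(popn, cfg$year, cfg$n_untracked,
                            seed = .sub_seed(cfg$seed, 4000 + k))
      untracked <- c(untracked, un)
      k <- k + 1
    }
    truth <- do.call(rbind, lapply(birds, function(b) {
      s <- b$schedule
      data.frame(bird_id = s$bird_id, population = s$population, sex = s$sex,
                 region = s$region, laying = format(s$laying_date),
                 hatch = format(s$hatch_date), depart = format(s$depart_date),
                 return_date = format(s$return_date))
    }))
    utils::write.csv(truth, out("truth.csv"), row.names = FALSE, quote = FALSE)
    manifest$stages$simulate <- list(
      n_tracked = length(birds), n_untracked = length(untracked))
  })

  ## -- geolocate -----------------------------------------------------------
  all_fixes <- list()
  stage("geolocate", {
    flagged <- 0
    for (id in names(birds)) {
      b <- birds[[id]]
      tw <- detect_twilights(b$light, threshold = cfg$threshold)
      s <- b$schedule
      win <- c(s$laying_date + 20, s$hatch_date + 20)
      cal <- calibrate_ea(tw, colony = s$colony, window = win,
                          grid = cfg$ea_grid)
      write_model_json(cal, out(paste0(id, "_calibration.json")))
      fx <- position_from_twilights(tw, ea = cal$ea)
      fx <- filter_track(fx, vmax = cfg$vmax)
      write_fixes_csv(fx, out(paste0(id, "_fixes.csv")), bird_id = id)
      flagged <- flagged + sum(!fx$retained)
      all_fixes[[id]] <- fx
    }
    manifest$stages$geolocate <- list(
      n_fixes = sum(vapply(all_fixes, nrow, integer(1))),
      n_flagged = flagged)
  })

  ## -- phenology -----------------------------------------------------------
  stage("phenology", {
    rows <- list()
    for (id in names(birds)) {
      b <- birds[[id]]
      s <- b$schedule
      dates <- s$days$date
      nights <- night_intervals(dates, s$colony[1], s$colony[2])
      daysiv <- day_intervals(dates, s$colony[1], s$colony[2])
      nv <- detect_night_visits(b$immersion, nights)
      dv <- detect_day_visits(b$light, daysiv, threshold = cfg$threshold)
      rows[[id]] <- phenology_summary(nv, dv, sex = s$sex, bird_id = id,
                                      exodus_min_days = cfg$exodus_min_days)
    }
    phen <- do.call(rbind, rows)
    write_phenology_csv(phen, out("phenology.csv"))
    manifest$stages$phenology <- list(n_birds = nrow(phen))
  })

  ## -- kde -----------------------------------------------------------------
  stage("kde", {
    pops <- vapply(birds, function(b) b$schedule$population, character(1))
    n_grids <- 0
    for (popn in unique(pops)) {
      ids <- names(birds)[pops == popn]
      pts <- list(); wts <- numeric(0)
      for (id in ids) {
        fx <- all_fixes[[id]]
        s <- birds[[id]]$schedule
        nb <- fx$retained & fx$date > s$depart_date & fx$date < s$return_date
        if (!any(nb)) next
        pp <- project_points(fx[nb, ])
        pts[[id]] <- pp
        wts <- c(wts, rep(1 / nrow(pp), nrow(pp)))  # birds weighted equally
      }
      if (length(pts) == 0) next
      xy <- do.call(rbind, pts)
      h <- plugin_bandwidth(xy)
      grid <- kernel_density(xy, h, cell_size = cfg$cell_km, weights = wts)
      ctr <- contour_levels(grid, levels = cfg$kde_levels)
      write_ascii_grid(grid, out(paste0("kde_", popn, ".asc")))
      write_contours_geojson(contour_polygons(grid, ctr),
                             out(paste0("kde_", popn, ".geojson")),
                             params = attr(xy, "params"))
      n_grids <- n_grids + 1
    }
    manifest$stages$kde <- list(n_grids = n_grids)
  })

  ## -- isotopes ------------------------------------------------------------
  stage("isotopes", {
    tracked_iso <- cohort_isotopes(
      lapply(birds, function(b) b$schedule), feather = "P6", tracked = TRUE,
      seed = .sub_seed(cfg$seed, 5000))
    untracked_iso <- cohort_isotopes(untracked, feather = "P6",
                                     tracked = FALSE,
                                     seed = .sub_seed(cfg$seed, 5001))
    write_isotope_csv(rbind(tracked_iso, untracked_iso), out("isotopes.csv"))
    model <- if (identical(cfg$classifier, "fit")) {
      tab <- table(tracked_iso$region)
      if (length(tab) < 2 || any(tab < 3)) {
        # tracked sample too small/one-sided to train on: fall back to the
        # published preset
        discriminant_preset("p6")
      } else fit_lda(tracked_iso)
    } else discriminant_preset(cfg$classifier)
    write_model_json(model, out("discriminant_model.json"))
    asg <- assign_untracked(model, untracked_iso)
    utils::write.csv(cbind(bird_id = untracked_iso$bird_id,
                           asg$predictions[setdiff(names(asg$predictions), "bird_id")]),
                     out("assignments.csv"), row.names = FALSE, quote = FALSE)
    manifest$stages$isotopes <- list(
      n_train = nrow(tracked_iso), n_assigned = nrow(untracked_iso),
      summary = asg$summary)
  })

  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Write the small deterministic fixtures used in tests and documentation
#'
#' Emits a 20-fix filter-cascade track with planted violations, a 12-point
#' Ward clustering set, an 8-point ellipse set, and one simulated bird-year
#' (light + immersion CSVs).
#'
#' @param out_dir writable directory.
#' @param seed seed for the bird-year.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(out_dir, "track_20fix.csv")
  utils::write.csv(fixture_track_20fix(), p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(out_dir, "ward_12pt.csv")
  utils::write.csv(fixture_ward_12pt(), p2, row.names = FALSE, quote = FALSE)
  p3 <- file.path(out_dir, "ellipse_8pt.csv")
  utils::write.csv(fixture_ellipse_8pt(), p3, row.names = FALSE, quote = FALSE)
  sched <- simulate_schedule("Menorca", 2012, seed = seed, sex = "M")
  li <- simulate_light(sched, cadence = 10, seed = .sub_seed(seed, 1))
  im <- simulate_immersion(sched, seed = .sub_seed(seed, 2))
  p4 <- write_light_csv(li, file.path(out_dir, "birdyear_light.csv"))
  p5 <- write_immersion_csv(im, file.path(out_dir, "birdyear_immersion.csv"))
  invisible(c(p1, p2, p3, p4, p5))
}

#' Bundled toy fixtures
#'
#' Deterministic miniature datasets used in tests and examples: a 20-fix
#' track with two latitude violations, one speed violation and three
#' equinox-window fixes (14 clean fixes); a 12-point two-cluster isotope
#' set; and an 8-point isotope scatter.
#'
#' @return data.frames.
#' @export
fixture_track_20fix <- function() {
  dates <- seq(as.Date("2012-02-22"), as.Date("2012-03-12"), by = "day")
  lon <- round(2 + 0.2 * (seq_along(dates) - 1), 1)
  lat <- rep(40, 20)
  lat[5] <- 55      # above the plausible band
  lat[9] <- 29.5    # below the plausible band
  lon[13] <- 20     # ~1500 km jump in one day: speed violation
  data.frame(
    bird_id = "fixture", date = dates,
    time = as.POSIXct(paste(dates, "12:00:00"), tz = "UTC"),
    lon = lon, lat = lat, lat_status = "ok", filters = "", retained = TRUE
  )
}

#' @rdname fixture_track_20fix
#' @export
fixture_ward_12pt <- function() {
  data.frame(
    bird_id = sprintf("w%02d", 1:12),
    d15N = c(11.2, 11.8, 12.1, 11.5, 12.4, 11.9,
             14.2, 14.8, 14.5, 15.1, 13.9, 14.6),
    d13C = c(-17.6, -17.2, -17.9, -17.4, -17.1, -17.7,
             -16.2, -15.9, -16.5, -16.1, -16.4, -15.8)
  )
}

#' @rdname fixture_track_20fix
#' @export
fixture_ellipse_8pt <- function() {
  data.frame(
    bird_id = sprintf("e%d", 1:8),
    d15N = c(12.0, 13.1, 11.4, 12.7, 13.5, 11.9, 12.3, 13.0),
    d13C = c(-17.0, -16.2, -17.5, -16.8, -16.0, -17.2, -16.5, -16.9)
  )
}
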