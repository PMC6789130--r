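# Plain-CSV/JSON interchange formats used between pipeline stages.

.ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

#' Write / read a light series CSV (`timestamp_utc,light`)
#'
#' @param series a light series data.frame (`timestamp`, `light`).
#' @param path file path.
#' @return `read_light_csv` returns a `light_series` data.frame.
#' @export
write_light_csv <- function(series, path) {
  utils::write.csv(
    data.frame(timestamp_utc = format(series$timestamp, .ts_fmt, tz = "UTC"),
               light = series$light),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_light_csv
#' @export
read_light_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(
    data.frame(timestamp = as.POSIXct(d$timestamp_utc, format = .ts_fmt, tz = "UTC"),
               light = d$light),
    class = c("light_series", "data.frame"))
}

#' Write / read an immersion series CSV (`timestamp_utc,wet_count`)
#'
#' @param series an immersion series data.frame (`timestamp`, `wet_count`).
#' @param path file path.
#' @export
write_immersion_csv <- function(series, path) {
  utils::write.csv(
    data.frame(timestamp_utc = format(series$timestamp, .ts_fmt, tz = "UTC"),
               wet_count = series$wet_count),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_immersion_csv
#' @export
read_immersion_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(
    data.frame(timestamp = as.POSIXct(d$timestamp_utc, format = .ts_fmt, tz = "UTC"),
               wet_count = as.integer(d$wet_count)),
    class = c("immersion_series", "data.frame"))
}

#' Write / read a fixes CSV (`bird_id,date,lon,lat,retained,filters`)
#'
#' @param fixes a `geo_fixes` data.frame.
#' @param path file path.
#' @param bird_id identifier written with each row.
#' @export
write_fixes_csv <- function(fixes, path, bird_id = NA) {
  utils::write.csv(
    data.frame(bird_id = bird_id, date = format(fixes$date),
               lon = round(fixes$lon, 5), lat = round(fixes$lat, 5),
               retained = fixes$retained, filters = fixes$filters),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(filters = "character"))
  d$date <- as.Date(d$date)
  d$filters[is.na(d$filters)] <- ""
  d
}

#' Write / read an isotope table CSV
#'
#' Columns `bird_id,population,feather,year,d15N,d13C,tracked,region`.
#'
#' @param samples isotope sample data.frame.
#' @param path file path.
#' @export
write_isotope_csv <- function(samples, path) {
  cols <- intersect(c("bird_id", "population", "feather", "year",
                      "d15N", "d13C", "tracked", "region"), names(samples))
  utils::write.csv(samples[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotope_csv
#' @export
read_isotope_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a phenology summary CSV
#'
#' @param summaries stacked [phenology_summary()] rows.
#' @param path file path.
#' @export
write_phenology_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a discriminant model (or calibration result) as JSON
#'
#' @param x a `discriminant_model` or `calibration_result`.
#' @param path file path.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = 10,
                       force = TRUE, matrix = "rowmajor")
  invisible(path)
}
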