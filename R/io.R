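#' Read a detection log file
#'
#' Reads a delimited-text dump of receiver detection logs: one row per
#' received tag pulse, carrying the tag id, the receiver (station) id, the
#' detection time and the received signal strength (RSSI). Column names in
#' the file are mapped through `columns`, so raw logger exports with
#' different headers can be read without editing.
#'
#' Times may be numeric (seconds since an epoch) or ISO-8601 date-times,
#' which are normalized to seconds since `time_origin` (parsed as UTC).
#' Malformed rows (unparseable time or RSSI, negative time) are dropped with
#' a reported count by default; `strict = TRUE` escalates them to an error
#' with line numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the required fields
#'   (`tag_id`, `station_id`, `time`, `rssi`) to the file's column names.
#' @param strict If `TRUE`, malformed rows are an error instead of being
#'   dropped.
#' @param time_origin Origin for ISO-8601 timestamps (date or date-time
#'   string, UTC).
#' @return A data frame with columns `tag_id`, `station_id`, `time`, `rssi`,
#'   sorted by (`tag_id`, `time`, `station_id`); the number of dropped rows is
#'   attached as attribute `n_bad_rows` and their file line numbers as
#'   `bad_rows`.
#' @export
read_detection_logs <- function(path,
                                columns = c(tag_id = "tag_id",
                                            station_id = "station_id",
                                            time = "time",
                                            rssi = "rssi"),
                                strict = FALSE,
                                time_origin = "2017-02-01") {
  if (!file.exists(path)) stop("log file not found: ", path, call. = FALSE)
  req <- c("tag_id", "station_id", "time", "rssi")
  if (!all(req %in% names(columns)))
    stop("`columns` must name tag_id, station_id, time and rssi", call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = columns[["time"]]))
  missing <- setdiff(unname(columns[req]), names(dt))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.table::data.table(
    tag_id = as.character(dt[[columns[["tag_id"]]]]),
    station_id = as.character(dt[[columns[["station_id"]]]]),
    time = parse_log_time(dt[[columns[["time"]]]], time_origin),
    rssi = suppressWarnings(as.numeric(dt[[columns[["rssi"]]]]))
  )
  bad <- which(!is.finite(out$time) | out$time < 0 | !is.finite(out$rssi))
  if (length(bad)) {
    if (strict)
      stop("malformed log row(s) at file line(s): ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    message(length(bad), " malformed log row(s) dropped from ", basename(path))
    out <- out[-bad]
  }
  data.table::setorder(out, tag_id, time, station_id)
  res <- as.data.frame(out)
  attr(res, "n_bad_rows") <- length(bad)
  attr(res, "bad_rows") <- bad + 1L
  res
}

## numeric seconds pass through; anything else is parsed as ISO-8601 UTC
parse_log_time <- function(x, time_origin) {
  num <- suppressWarnings(as.numeric(x))
  iso <- is.na(num) & !is.na(x) & nzchar(x)
  if (any(iso)) {
    origin <- as.POSIXct(time_origin, tz = "UTC")
    xs <- sub("T", " ", x[iso], fixed = TRUE)
    parsed <- as.POSIXct(xs, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
    date_only <- is.na(parsed)
    if (any(date_only))
      parsed[date_only] <- as.POSIXct(xs[date_only], tz = "UTC",
                                      format = "%Y-%m-%d")
    num[iso] <- as.numeric(parsed) - as.numeric(origin)
  }
  num
}

#' Read a station array from delimited files
#'
#' @param stations_path Delimited file with columns `station_id`, `x`, `y`
#'   (planar coordinates, metres).
#' @param homes_path Delimited file with columns `tag_id`, `station_id`
#'   mapping each tag to its home station.
#' @return A [station_array()].
#' @export
read_station_array <- function(stations_path, homes_path) {
  for (p in c(stations_path, homes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  st <- as.data.frame(data.table::fread(stations_path))
  if (!all(c("station_id", "x", "y") %in% names(st)))
    stop("stations file must have columns station_id, x, y", call. = FALSE)
  st$x <- suppressWarnings(as.numeric(st$x))
  st$y <- suppressWarnings(as.numeric(st$y))
  hm <- as.data.frame(data.table::fread(homes_path))
  if (!all(c("tag_id", "station_id") %in% names(hm)))
    stop("homes file must have columns tag_id, station_id", call. = FALSE)
  home_of <- setNames(as.character(hm$station_id), as.character(hm$tag_id))
  if (anyDuplicated(names(home_of)))
    stop("duplicate tag id(s) in home map", call. = FALSE)
  station_array(st, home_of)
}

foray_columns <- c("tag_id", "start_time", "end_time", "duration_min",
                   "max_distance_m", "round_trip_m", "n_known_epochs",
                   "censored")

#' Write / read a foray table
#'
#' Forays are persisted as CSV with the fixed column set `tag_id`,
#' `start_time`, `end_time`, `duration_min`, `max_distance_m`,
#' `round_trip_m`, `n_known_epochs`, `censored`. Numeric values are written
#' at full precision so that a write-then-read round trip reproduces the
#' records exactly.
#'
#' @param forays A foray table from [detect_forays()].
#' @param path Output CSV path.
#' @return `write_forays()` returns `path` invisibly; `read_forays()` returns
#'   the foray data frame.
#' @export
write_forays <- function(forays, path) {
  forays <- as.data.frame(forays)
  missing <- setdiff(foray_columns, names(forays))
  if (length(missing))
    stop("foray table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- forays[, foray_columns]
  ## write doubles with 17 significant digits so re-reading is the identity
  for (col in c("start_time", "end_time", "duration_min", "max_distance_m",
                "round_trip_m")) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- ""
    out[[col]] <- v
  }
  data.table::fwrite(out, path, logical01 = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forays
#' @export
read_forays <- function(path) {
  if (!file.exists(path)) stop("foray file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path,
                          colClasses = list(character = "tag_id",
                                            logical = "censored"))
  missing <- setdiff(foray_columns, names(dt))
  if (length(missing))
    stop("foray file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- as.data.frame(dt)[, foray_columns]
  for (col in c("start_time", "end_time", "duration_min", "max_distance_m",
                "round_trip_m"))
    out[[col]] <- as.numeric(out[[col]])
  out$n_known_epochs <- as.integer(out$n_known_epochs)
  out
}
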