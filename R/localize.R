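#' Window a tag's detection logs into per-station mean RSSI
#'
#' Slices one tag's detection-log stream into overlapping moving windows
#' (default 15 s wide, advanced in 5-s steps) and computes the mean RSSI per
#' station within each window. Windows cover the half-open interval
#' `[epoch_start, epoch_start + window_width)`; the window grid is anchored
#' at the tag's first log time rounded down to a multiple of `step` and runs
#' to its last log time.
#'
#' @param logs Detection logs for a single tag (columns `station_id`, `time`,
#'   `rssi`; a `tag_id` column, if present, must contain one tag).
#' @param config An [analysis_config()].
#' @return A data frame with columns `epoch_start`, `station_id`,
#'   `mean_rssi`, one row per (window, station with logs), sorted by
#'   `epoch_start` then `station_id`. Windows with no logs are absent. Empty
#'   input yields a zero-row frame.
#' @export
window_logs <- function(logs, config = analysis_config()) {
  logs <- as.data.frame(logs)
  if ("tag_id" %in% names(logs) && length(unique(logs$tag_id)) > 1)
    stop("`logs` must contain a single tag; got ",
         length(unique(logs$tag_id)), call. = FALSE)
  empty <- data.frame(epoch_start = numeric(), station_id = character(),
                      mean_rssi = numeric())
  if (!nrow(logs)) return(empty)
  step <- config$step
  width <- config$window_width
  dt <- data.table::data.table(
    station_id = as.character(logs$station_id),
    time = as.numeric(logs$time),
    rssi = as.numeric(logs$rssi)
  )
  anchor <- floor(min(dt$time) / step) * step
  ## a log at time t falls in every grid window with epoch in (t - width, t]
  k <- 0:(ceiling(width / step) - 1L)
  expanded <- dt[rep(seq_len(nrow(dt)), each = length(k))]
  expanded[, epoch_start := floor(time / step) * step - rep(k * step, nrow(dt))]
  expanded <- expanded[epoch_start >= anchor & epoch_start > time - width &
                         epoch_start <= time]
  win <- expanded[, .(mean_rssi = mean(rssi)), by = .(epoch_start, station_id)]
  data.table::setorder(win, epoch_start, station_id)
  as.data.frame(win)
}

#' Assign a best-estimate location for one window
#'
#' Applies the conservative location decision tree to a single window's
#' per-station mean RSSI map: (1) no logs at all gives `unknown`; (2) logs
#' from exactly one station give that station; (3) logs from several
#' stations, none of them home, give the station with the highest mean RSSI;
#' (4) logs from several stations including home give home if the home
#' station's window mean exceeds `config$home_rssi_threshold`, and otherwise
#' the station with the highest mean RSSI (which may itself be home).
#'
#' Exact ties in mean RSSI are broken in favour of the station of the
#' previous known estimate, then the lexicographically smallest station id.
#'
#' @param window_means Named numeric vector of per-station mean RSSI for the
#'   window (possibly empty).
#' @param home_station The tag's home station id.
#' @param config An [analysis_config()].
#' @param previous Station id of the previous known estimate (or `NULL`),
#'   used only for tie-breaking.
#' @return A list with elements `status` (`"known"`/`"unknown"`),
#'   `station_id`, `mean_rssi` and `is_home`.
#' @export
assign_location <- function(window_means, home_station,
                            config = analysis_config(), previous = NULL) {
  if (!is.null(previous) && !is.character(previous))
    previous <- as.character(previous$station_id %||% NA_character_)
  if (length(window_means) == 0)
    return(list(status = "unknown", station_id = NA_character_,
                mean_rssi = NA_real_, is_home = FALSE))
  if (is.null(names(window_means)) || anyDuplicated(names(window_means)))
    stop("`window_means` must be named by unique station ids", call. = FALSE)
  station <- if (length(window_means) == 1) {
    names(window_means)
  } else if (home_station %in% names(window_means) &&
             window_means[[home_station]] > config$home_rssi_threshold) {
    home_station
  } else {
    tied <- names(window_means)[window_means == max(window_means)]
    if (!is.null(previous) && !is.na(previous) && previous %in% tied) previous
    else min(tied)
  }
  list(status = "known", station_id = station,
       mean_rssi = unname(window_means[[station]]),
       is_home = identical(station, home_station))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Localize one tag over its full log stream
#'
#' Converts a tag's detection logs into a dense per-epoch series of
#' best-estimate locations: windows are formed with [window_logs()], each is
#' assigned via the [assign_location()] decision tree, and epochs without any
#' logs (including gaps between the first and last log) are emitted with
#' status `unknown`. Each estimate stands for the `step`-long epoch beginning
#' at its `epoch_start`. The result is invariant to the row order of `logs`.
#'
#' @param logs Detection logs (data frame with `tag_id`, `station_id`,
#'   `time`, `rssi`). Rows for other tags are ignored when `tag_id` is given.
#' @param array A [station_array()] mapping the tag to its home station.
#' @param tag_id Tag to localize; may be omitted when `logs` holds one tag.
#' @param config An [analysis_config()].
#' @return A data frame with one row per epoch: `tag_id`, `epoch_start`,
#'   `status`, `station_id`, `mean_rssi`, `is_home`.
#' @export
localize_tag <- function(logs, array, tag_id = NULL,
                         config = analysis_config()) {
  logs <- as.data.frame(logs)
  if (is.null(tag_id)) {
    tags <- unique(as.character(logs$tag_id))
    if (length(tags) != 1)
      stop("`logs` holds ", length(tags), " tags; supply `tag_id`",
           call. = FALSE)
    tag_id <- tags
  } else if ("tag_id" %in% names(logs)) {
    logs <- logs[logs$tag_id == tag_id, , drop = FALSE]
  }
  home <- home_station(array, tag_id)
  empty <- data.frame(tag_id = character(), epoch_start = numeric(),
                      status = character(), station_id = character(),
                      mean_rssi = numeric(), is_home = logical())
  if (!nrow(logs)) return(empty)
  unknown_st <- setdiff(unique(as.character(logs$station_id)),
                        rownames(array$coords))
  if (length(unknown_st))
    stop("log station id(s) not in array: ",
         paste(unknown_st, collapse = ", "), call. = FALSE)

  win <- data.table::as.data.table(window_logs(logs, config))
  step <- config$step
  epochs <- seq(min(win$epoch_start), max(win$epoch_start), by = step)

  ## per-epoch window summaries
  data.table::setorder(win, epoch_start, -mean_rssi, station_id)
  top <- win[!duplicated(epoch_start),
             .(epoch_start, best_station = station_id, max_mean = mean_rssi)]
  counts <- win[, .(n_stations = .N), by = epoch_start]
  homes <- win[station_id == home, .(epoch_start, home_mean = mean_rssi)]
  at_max <- win[top, on = "epoch_start"][mean_rssi == max_mean]
  ties <- at_max[, .(n_at_max = .N), by = epoch_start]

  et <- data.table::data.table(epoch_start = epochs)
  for (tab in list(top, counts, homes, ties))
    et <- merge(et, tab, by = "epoch_start", all.x = TRUE)
  et[is.na(n_stations), n_stations := 0L]
  et[is.na(n_at_max), n_at_max := 0L]

  known <- et$n_stations > 0L
  home_override <- known & et$n_stations > 1L & !is.na(et$home_mean) &
    et$home_mean > config$home_rssi_threshold
  station <- rep(NA_character_, nrow(et))
  station[known] <- et$best_station[known]
  station[home_override] <- home

  ## exact-tie resolution: prefer the previous known estimate's station
  unresolved <- which(known & !home_override & et$n_stations > 1L &
                        et$n_at_max > 1L)
  if (length(unresolved)) {
    tied_sets <- split(at_max$station_id, at_max$epoch_start)
    for (i in unresolved) {
      before <- station[seq_len(i - 1L)]
      before <- before[!is.na(before)]
      prev <- if (length(before)) before[length(before)] else NA_character_
      set <- tied_sets[[as.character(et$epoch_start[i])]]
      if (!is.na(prev) && prev %in% set) station[i] <- prev
    }
  }

  ## mean RSSI of the assigned station
  lookup <- win[data.table::data.table(epoch_start = et$epoch_start,
                                       station_id = station),
                on = c("epoch_start", "station_id"), mean_rssi]
  data.frame(
    tag_id = tag_id,
    epoch_start = et$epoch_start,
    status = ifelse(known, "known", "unknown"),
    station_id = station,
    mean_rssi = lookup,
    is_home = !is.na(station) & station == home,
    stringsAsFactors = FALSE
  )
}

#' Localize every tag in a detection log
#'
#' Convenience wrapper running [localize_tag()] for each tag with a home
#' mapping in `array`.
#'
#' @inheritParams localize_tag
#' @return Row-bound location estimates for all tags.
#' @export
localize_all <- function(logs, array, config = analysis_config()) {
  tags <- intersect(unique(as.character(logs$tag_id)), names(array$home_of))
  out <- lapply(tags, function(tg) localize_tag(logs, array, tg, config))
  do.call(rbind, out)
}
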