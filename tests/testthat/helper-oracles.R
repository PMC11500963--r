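# Brute-force reference implementations used to validate the vectorized
# pipeline, plus random-instance generators. These re-derive every window
# and every run from first principles, independently of the package code.

# Naive per-epoch localization: subset the logs of each window directly and
# apply the decision-tree rules literally.
oracle_localize <- function(logs, array, tag, config) {
  logs <- logs[logs$tag_id == tag, , drop = FALSE]
  home <- home_station(array, tag)
  step <- config$step
  width <- config$window_width
  thr <- config$home_rssi_threshold
  anchor <- floor(min(logs$time) / step) * step
  epochs <- seq(anchor, floor(max(logs$time) / step) * step, by = step)
  prev <- NA_character_
  rows <- lapply(epochs, function(e) {
    sel <- logs$time >= e & logs$time < e + width
    if (!any(sel)) {
      return(data.frame(tag_id = tag, epoch_start = e, status = "unknown",
                        station_id = NA_character_, mean_rssi = NA_real_,
                        is_home = FALSE))
    }
    means <- tapply(logs$rssi[sel], logs$station_id[sel], mean)
    if (length(means) == 1) {
      st <- names(means)
    } else if (home %in% names(means) && means[[home]] > thr) {
      st <- home
    } else {
      tied <- sort(names(means)[means == max(means)])
      st <- if (!is.na(prev) && prev %in% tied) prev else tied[1]
    }
    prev <<- st
    data.frame(tag_id = tag, epoch_start = e, status = "known",
               station_id = st, mean_rssi = unname(means[[st]]),
               is_home = st == home)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Naive foray scan: walk the epoch sequence once, opening a run at a known
# non-home epoch and closing it at the next known home epoch, then evaluate
# both criteria per run.
oracle_forays <- function(est, array, home, config) {
  est <- est[order(est$epoch_start), , drop = FALSE]
  runs <- list()
  open <- FALSE
  seen_home <- FALSE
  start <- NA_real_
  stations <- character()
  started_before_home <- FALSE
  for (i in seq_len(nrow(est))) {
    if (est$status[i] != "known") next
    if (est$is_home[i]) {
      if (open) {
        runs[[length(runs) + 1]] <- list(
          start = start, end = est$epoch_start[i], stations = stations,
          censored = started_before_home)
        open <- FALSE
      }
      seen_home <- TRUE
    } else {
      if (!open) {
        open <- TRUE
        start <- est$epoch_start[i]
        stations <- character()
        started_before_home <- !seen_home
      }
      stations <- c(stations, est$station_id[i])
    }
  }
  if (open)
    runs[[length(runs) + 1]] <- list(start = start, end = NA_real_,
                                     stations = stations, censored = TRUE)
  rows <- lapply(runs, function(r) {
    dmax <- max(station_distance(array, rep(home, length(r$stations)),
                                 r$stations))
    if (!(config$step * length(r$stations) > config$min_nonhome_time)) return(NULL)
    if (!(dmax > config$distance_threshold)) return(NULL)
    data.frame(tag_id = est$tag_id[1], start_time = r$start, end_time = r$end,
               duration_min = (r$end - r$start) / 60,
               max_distance_m = dmax, round_trip_m = 2 * dmax,
               n_known_epochs = length(r$stations), censored = r$censored)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(tag_id = character(), start_time = numeric(),
                      end_time = numeric(), duration_min = numeric(),
                      max_distance_m = numeric(), round_trip_m = numeric(),
                      n_known_epochs = integer(), censored = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# A small random array with a designated home station for tag "t1".
random_test_array <- function(n_stations = 6) {
  ids <- sprintf("S%d", seq_len(n_stations))
  station_array(
    data.frame(station_id = ids,
               x = runif(n_stations, 0, 600),
               y = runif(n_stations, 0, 600)),
    home_of = c(t1 = ids[1])
  )
}

# Random detection-log instance; integer RSSI so window means are computed
# exactly by any summation order (this also exercises exact-tie handling).
random_logs <- function(array, n_logs, t_max = 600) {
  ids <- array$stations$station_id
  data.frame(
    tag_id = "t1",
    station_id = sample(ids, n_logs, replace = TRUE),
    time = round(runif(n_logs, 0, t_max), 1),
    rssi = as.numeric(sample(-40:-1, n_logs, replace = TRUE))
  )
}

# Random dense estimate series over the array's stations.
random_estimates <- function(array, n_epochs, step = 5,
                             p_unknown = 0.2, p_home = 0.4) {
  ids <- array$stations$station_id
  home <- array$home_of[["t1"]]
  status <- sample(c("unknown", "home", "away"), n_epochs, replace = TRUE,
                   prob = c(p_unknown, p_home, 1 - p_unknown - p_home))
  station <- ifelse(status == "unknown", NA_character_,
                    ifelse(status == "home", home,
                           sample(setdiff(ids, home), n_epochs, replace = TRUE)))
  data.frame(
    tag_id = "t1",
    epoch_start = (seq_len(n_epochs) - 1) * step,
    status = ifelse(status == "unknown", "unknown", "known"),
    station_id = station,
    mean_rssi = ifelse(is.na(station), NA_real_, -20),
    is_home = !is.na(station) & station == home
  )
}

expect_same_forays <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    ord_a <- order(a$start_time)
    ord_b <- order(b$start_time)
    for (col in c("start_time", "end_time", "duration_min", "max_distance_m",
                  "round_trip_m", "n_known_epochs", "censored"))
      expect_equal(a[[col]][ord_a], b[[col]][ord_b], tolerance = 1e-12)
  }
}
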