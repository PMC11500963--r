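#' Simulator configuration
#'
#' Parameters of the ground-truthed synthetic deployment generator. The
#' defaults emulate the study system the pipeline was designed for: 35
#' receiver stations at territory centres with a mean neighbour spacing of
#' 93.7 m, 27 tagged birds (13 males, 14 females) tracked for 37 days with
#' tags pulsing every 5 s, birds mostly at their home-territory centre with
#' Poisson-rate extra-territorial forays of log-normal duration (median
#' about 5.7 min) and log-normal one-way distance (median about 324 m), and
#' sex-specific foray rates (females 0.8/day, males 1.4/day; ratio 1.75,
#' population mean about 1.09 forays/day). RSSI decays linearly in log10
#' distance with Gaussian noise, and detection probability falls off
#' logistically with distance, range-limiting the array.
#'
#' @param n_stations Number of receiver stations (>= 2).
#' @param neighbour_spacing Target mean nearest-neighbour station spacing, m.
#' @param array_jitter_frac Station-position jitter (SD as a fraction of
#'   `neighbour_spacing`) applied to the regular grid.
#' @param n_males,n_females Number of tagged birds per sex.
#' @param deployment_days Tracking duration per bird, days.
#' @param pulse_interval Tag pulse interval, s.
#' @param foray_rate Named vector `c(female = , male = )` of foray rates per
#'   day.
#' @param foray_duration_meanlog,foray_duration_sdlog Log-normal parameters
#'   of foray duration, seconds.
#' @param foray_distance_meanlog,foray_distance_sdlog Log-normal parameters
#'   of one-way foray distance, metres.
#' @param foray_target `"point"` (target at the drawn distance in a uniform
#'   random direction) or `"station"` (target snapped to a station at least
#'   `foray_station_min_distance` from home; used for validation scenarios
#'   where every foray must be observable).
#' @param foray_station_min_distance Minimum home-target station distance in
#'   `"station"` mode, m.
#' @param speed Travel speed during forays, m/s (straight-line travel).
#' @param home_jitter_sd SD of positional jitter around the modelled path, m.
#' @param rssi_intercept,rssi_slope,rssi_noise_sd Log-distance path-loss
#'   model of RSSI: `intercept + slope * log10(d) + N(0, noise_sd)`. The
#'   defaults put the mean RSSI at 50 m at the deployed home-override
#'   threshold of -11.484.
#' @param detection_midpoint,detection_scale Logistic detection probability
#'   `plogis((midpoint - d) / scale)`: certain detection well inside
#'   `midpoint` metres, negligible well beyond.
#' @param provisioning List of provisioning-observation parameters:
#'   `baseline_feeds_per_hour`, `beta_tradeoff` (log-scale effect of the
#'   trailing foray rate on feed rate), `beta_brood_size`, `beta_brood_age`,
#'   `sex_effect_male`, `bird_sd` (random-intercept SD), `obs_hours`,
#'   `window_days`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_stations = 35,
                       neighbour_spacing = 93.7,
                       array_jitter_frac = 0.05,
                       n_males = 13,
                       n_females = 14,
                       deployment_days = 37,
                       pulse_interval = 5,
                       foray_rate = c(female = 0.8, male = 1.4),
                       foray_duration_meanlog = log(5.67 * 60),
                       foray_duration_sdlog = 1.54,
                       foray_distance_meanlog = log(324),
                       foray_distance_sdlog = 0.46,
                       foray_target = c("point", "station"),
                       foray_station_min_distance = 500,
                       speed = 5,
                       home_jitter_sd = 5,
                       rssi_intercept = 30.99,
                       rssi_slope = -25,
                       rssi_noise_sd = 4,
                       detection_midpoint = 70,
                       detection_scale = 15,
                       provisioning = list()) {
  prov <- utils::modifyList(
    list(baseline_feeds_per_hour = 3, beta_tradeoff = -0.3,
         beta_brood_size = 0.4, beta_brood_age = 0.1,
         sex_effect_male = -0.5, bird_sd = 0.3, obs_hours = 3,
         window_days = 3),
    provisioning
  )
  cfg <- list(
    n_stations = as.integer(n_stations),
    neighbour_spacing = neighbour_spacing,
    array_jitter_frac = array_jitter_frac,
    n_males = as.integer(n_males),
    n_females = as.integer(n_females),
    deployment_days = deployment_days,
    pulse_interval = pulse_interval,
    foray_rate = foray_rate,
    foray_duration_meanlog = foray_duration_meanlog,
    foray_duration_sdlog = foray_duration_sdlog,
    foray_distance_meanlog = foray_distance_meanlog,
    foray_distance_sdlog = foray_distance_sdlog,
    foray_target = match.arg(foray_target),
    foray_station_min_distance = foray_station_min_distance,
    speed = speed,
    home_jitter_sd = home_jitter_sd,
    rssi_intercept = rssi_intercept,
    rssi_slope = rssi_slope,
    rssi_noise_sd = rssi_noise_sd,
    detection_midpoint = detection_midpoint,
    detection_scale = detection_scale,
    provisioning = prov
  )
  if (cfg$n_stations < 2) stop("need at least 2 stations", call. = FALSE)
  if (cfg$pulse_interval <= 0) stop("`pulse_interval` must be > 0", call. = FALSE)
  if (!all(c("female", "male") %in% names(cfg$foray_rate)))
    stop("`foray_rate` must be named c(female=, male=)", call. = FALSE)
  if (any(cfg$foray_rate < 0)) stop("foray rates must be >= 0", call. = FALSE)
  if (cfg$deployment_days <= 0) stop("`deployment_days` must be > 0", call. = FALSE)
  if (cfg$speed <= 0) stop("`speed` must be > 0", call. = FALSE)
  structure(cfg, class = c("sim_config", "list"))
}

bird_ids <- function(config) {
  c(sprintf("M%02d", seq_len(config$n_males)),
    sprintf("F%02d", seq_len(config$n_females)))
}
bird_sexes <- function(config) {
  setNames(c(rep("M", config$n_males), rep("F", config$n_females)),
           bird_ids(config))
}

#' Generate a synthetic receiver array
#'
#' Lays `n_stations` stations on a jittered square grid with the configured
#' neighbour spacing (mean nearest-neighbour distance within about 10% of
#' `neighbour_spacing`) and assigns each simulated bird a home station.
#' With exactly 2 stations they are placed exactly `neighbour_spacing`
#' apart (jitter suppressed).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the array exactly.
#' @return A [station_array()] with one home station per simulated bird.
#' @export
make_array <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_stations
  s <- config$neighbour_spacing
  birds <- bird_ids(config)
  if (length(birds) > n)
    stop("more birds (", length(birds), ") than stations (", n,
         "): infeasible array", call. = FALSE)
  set.seed(substream_seed(seed, "array"))
  if (n == 2) {
    xy <- cbind(c(0, s), c(0, 0))
  } else {
    nc <- ceiling(sqrt(n))
    nr <- ceiling(n / nc)
    grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[seq_len(n), ]
    xy <- cbind((grid$col - 1) * s, (grid$row - 1) * s) +
      matrix(rnorm(2 * n, 0, config$array_jitter_frac * s), ncol = 2)
  }
  stations <- data.frame(
    station_id = sprintf("S%02d", seq_len(n)),
    x = xy[, 1], y = xy[, 2]
  )
  candidates <- stations$station_id
  if (config$foray_target == "station") {
    ## homes must have an observable far target station
    d <- as.matrix(stats::dist(xy))
    candidates <- stations$station_id[
      apply(d, 1, max) >= config$foray_station_min_distance]
    if (length(candidates) < length(birds))
      stop("only ", length(candidates), " station(s) have another station >= ",
           config$foray_station_min_distance,
           " m away: infeasible for ", length(birds), " birds", call. = FALSE)
  }
  home_of <- setNames(sample(candidates, length(birds)), birds)
  arr <- station_array(stations, home_of)
  spacing <- nn_spacing(arr)
  if (n > 2 && abs(spacing - s) > 0.10 * s)
    stop(sprintf(
      "array spacing infeasible: realised mean nearest-neighbour %.1f m vs target %.1f m",
      spacing, s), call. = FALSE)
  arr
}

#' Simulate bird movement with ground-truth forays
#'
#' Each bird sits at its home-territory centre except during forays, drawn
#' as a Poisson process with its sex-specific daily rate. Each foray has a
#' log-normal one-way distance and duration; the bird travels to the target
#' in a straight line at constant speed, dwells there, and returns. Forays
#' are kept only if fully inside the deployment (with a 2-min margin) and
#' separated by at least 2 min, so truth intervals are disjoint.
#'
#' @param array A [make_array()] result (station array with bird homes).
#' @param config A [sim_config()].
#' @param seed Integer seed; per-bird substreams make the truth reproducible
#'   bird by bird.
#' @return An object of class `foray_movement`: list with `array`, `config`,
#'   `deployment` (tag_id, sex, home, start, end in seconds; time 0 is local
#'   midnight of day 1), and `truth` (one row per true foray: `tag_id`,
#'   `sex`, `start`, `end`, `duration_s`, `distance_m` one-way, `target_x`,
#'   `target_y`).
#' @export
simulate_movement <- function(array, config = sim_config(), seed = 1) {
  stopifnot(inherits(array, "station_array"), inherits(config, "sim_config"))
  birds <- bird_ids(config)
  sexes <- bird_sexes(config)
  days <- config$deployment_days
  dep_end <- days * 86400 - 1
  deployment <- data.frame(
    tag_id = birds, sex = unname(sexes[birds]),
    home = unname(array$home_of[birds]),
    start = 0, end = dep_end, stringsAsFactors = FALSE
  )
  margin <- 120
  truth <- lapply(seq_along(birds), function(i) {
    tg <- birds[i]
    set.seed(substream_seed(seed, "movement", i))
    rate <- if (sexes[[tg]] == "M") config$foray_rate[["male"]] else
      config$foray_rate[["female"]]
    n <- rpois(1, rate * days)
    if (n == 0) return(NULL)
    start <- sort(runif(n, margin, dep_end - margin))
    dur <- rlnorm(n, config$foray_duration_meanlog, config$foray_duration_sdlog)
    home_xy <- array$coords[deployment$home[i], ]
    if (config$foray_target == "station") {
      cand <- rownames(array$coords)[
        station_distance(array, rep(deployment$home[i], nrow(array$coords)),
                         rownames(array$coords)) >=
          config$foray_station_min_distance]
      if (!length(cand))
        stop("no station >= ", config$foray_station_min_distance,
             " m from home of ", tg, call. = FALSE)
      target_st <- sample(cand, n, replace = TRUE)
      tx <- array$coords[target_st, 1]
      ty <- array$coords[target_st, 2]
      dist <- sqrt((tx - home_xy[1])^2 + (ty - home_xy[2])^2)
    } else {
      dist <- rlnorm(n, config$foray_distance_meanlog,
                     config$foray_distance_sdlog)
      theta <- runif(n, 0, 2 * pi)
      tx <- home_xy[1] + dist * cos(theta)
      ty <- home_xy[2] + dist * sin(theta)
    }
    ## duration at least the round-trip travel time plus a short dwell
    dur <- pmax(dur, 2 * dist / config$speed + 2 * config$pulse_interval)
    end <- start + dur
    keep <- end <= dep_end - margin
    ## enforce disjoint forays with a 2-min gap (greedy, earliest first)
    last_end <- -Inf
    for (j in seq_len(n)) {
      if (!keep[j]) next
      if (start[j] < last_end + margin) keep[j] <- FALSE
      else last_end <- end[j]
    }
    if (!any(keep)) return(NULL)
    data.frame(tag_id = tg, sex = sexes[[tg]],
               start = start[keep], end = end[keep],
               duration_s = dur[keep], distance_m = dist[keep],
               target_x = unname(tx[keep]), target_y = unname(ty[keep]),
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(tag_id = character(), sex = character(),
                        start = numeric(), end = numeric(),
                        duration_s = numeric(), distance_m = numeric(),
                        target_x = numeric(), target_y = numeric())
  rownames(truth) <- NULL
  structure(list(array = array, config = config, deployment = deployment,
                 truth = truth, seed = seed),
            class = "foray_movement")
}

#' @export
print.foray_movement <- function(x, ...) {
  cat(sprintf(
    "Simulated movement: %d birds, %g days, %d true forays\n",
    nrow(x$deployment), x$config$deployment_days, nrow(x$truth)))
  invisible(x)
}

#' True positions of a bird at given times
#'
#' Evaluates the modelled (noise-free) path of one bird: home-territory
#' centre outside forays, piecewise-linear out/dwell/return during them.
#'
#' @param movement A [simulate_movement()] result.
#' @param tag_id Bird id.
#' @param times Numeric vector of times (s).
#' @return A two-column matrix of x/y coordinates (m).
#' @export
positions_at <- function(movement, tag_id, times) {
  stopifnot(inherits(movement, "foray_movement"))
  dep <- movement$deployment
  i <- match(tag_id, dep$tag_id)
  if (is.na(i)) stop("unknown bird: ", tag_id, call. = FALSE)
  home_xy <- movement$array$coords[dep$home[i], ]
  x <- rep(home_xy[1], length(times))
  y <- rep(home_xy[2], length(times))
  tr <- movement$truth[movement$truth$tag_id == tag_id, , drop = FALSE]
  v <- movement$config$speed
  for (j in seq_len(nrow(tr))) {
    sel <- times >= tr$start[j] & times < tr$end[j]
    if (!any(sel)) next
    t_rel <- times[sel] - tr$start[j]
    d <- tr$distance_m[j]
    t_out <- d / v
    dur <- tr$end[j] - tr$start[j]
    frac <- ifelse(t_rel < t_out, t_rel * v / d,
                   ifelse(t_rel < dur - t_out, 1,
                          pmax(0, dur - t_rel) * v / d))
    x[sel] <- home_xy[1] + frac * (tr$target_x[j] - home_xy[1])
    y[sel] <- home_xy[2] + frac * (tr$target_y[j] - home_xy[2])
  }
  cbind(x = x, y = y)
}

#' Simulate receiver detection logs
#'
#' For every tag pulse and every station, the pulse is detected with
#' probability `plogis((detection_midpoint - d) / detection_scale)` where `d`
#' is the tag-station distance; detected pulses are logged with
#' `rssi = rssi_intercept + rssi_slope * log10(d) + N(0, rssi_noise_sd)`.
#' Positional jitter (`home_jitter_sd`) is added to the modelled path before
#' distances are computed. Per-tag random substreams make the logs for any
#' subset of tags identical to those generated for the full deployment.
#'
#' @param movement A [simulate_movement()] result.
#' @param seed Integer seed.
#' @param tags Tags to simulate (default: all).
#' @return A detection-log data frame (`tag_id`, `station_id`, `time`,
#'   `rssi`) sorted by (`tag_id`, `time`, `station_id`).
#' @export
simulate_logs <- function(movement, seed = 1, tags = NULL) {
  stopifnot(inherits(movement, "foray_movement"))
  cfg <- movement$config
  dep <- movement$deployment
  if (is.null(tags)) tags <- dep$tag_id
  coords <- movement$array$coords
  sx <- coords[, 1]
  sy <- coords[, 2]
  st_ids <- rownames(coords)
  out <- vector("list", length(tags))
  for (ti in seq_along(tags)) {
    tg <- tags[ti]
    i <- match(tg, dep$tag_id)
    if (is.na(i)) stop("unknown bird: ", tg, call. = FALSE)
    set.seed(substream_seed(seed, "logs", i))
    times <- seq(dep$start[i], dep$end[i], by = cfg$pulse_interval)
    day_of <- floor(times / 86400)
    chunks <- split(times, day_of)
    tag_logs <- vector("list", length(chunks))
    for (ci in seq_along(chunks)) {
      tt <- chunks[[ci]]
      pos <- positions_at(movement, tg, tt)
      px <- pos[, 1] + rnorm(length(tt), 0, cfg$home_jitter_sd)
      py <- pos[, 2] + rnorm(length(tt), 0, cfg$home_jitter_sd)
      d <- sqrt(outer(px, sx, "-")^2 + outer(py, sy, "-")^2)
      p <- plogis((cfg$detection_midpoint - d) / cfg$detection_scale)
      hit <- which(runif(length(p)) < p)
      if (!length(hit)) next
      dhit <- pmax(d[hit], 1)
      tag_logs[[ci]] <- data.table::data.table(
        tag_id = tg,
        station_id = st_ids[((hit - 1L) %/% length(tt)) + 1L],
        time = tt[((hit - 1L) %% length(tt)) + 1L],
        rssi = cfg$rssi_intercept + cfg$rssi_slope * log10(dhit) +
          rnorm(length(hit), 0, cfg$rssi_noise_sd)
      )
    }
    out[[ti]] <- data.table::rbindlist(tag_logs)
  }
  logs <- data.table::rbindlist(out)
  if (!nrow(logs))
    return(data.frame(tag_id = character(), station_id = character(),
                      time = numeric(), rssi = numeric()))
  data.table::setorder(logs, tag_id, time, station_id)
  as.data.frame(logs)
}

#' Ground-truth daily foray counts
#'
#' Per bird-day counts of true forays (counted on the civil day of their
#' start), including zero days across the whole deployment.
#'
#' @param movement A [simulate_movement()] result.
#' @return A data frame with `tag_id`, `sex`, `date` (day index), `n_forays`.
#' @export
truth_daily_counts <- function(movement) {
  stopifnot(inherits(movement, "foray_movement"))
  dep <- movement$deployment
  grid <- do.call(rbind, lapply(seq_len(nrow(dep)), function(i) {
    data.frame(tag_id = dep$tag_id[i], sex = dep$sex[i],
               date = seq(floor(dep$start[i] / 86400),
                          floor(dep$end[i] / 86400)),
               stringsAsFactors = FALSE)
  }))
  tr <- movement$truth
  if (nrow(tr)) {
    counts <- stats::aggregate(
      list(n_forays = tr$start),
      by = list(tag_id = tr$tag_id, date = floor(tr$start / 86400)),
      FUN = length)
    grid <- merge(grid, counts, by = c("tag_id", "date"), all.x = TRUE)
  } else {
    grid$n_forays <- NA_integer_
  }
  grid$n_forays[is.na(grid$n_forays)] <- 0L
  grid[order(grid$tag_id, grid$date), c("tag_id", "sex", "date", "n_forays")]
}

#' Draw daily foray counts without simulating telemetry
#'
#' Truth-level generator for power and coverage studies of the provisioning
#' trade-off: per-bird daily foray counts drawn directly as Poisson with the
#' sex-specific rates in `config`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_males,n_females Override the bird counts in `config`.
#' @param days Number of days (default `config$deployment_days`).
#' @return A data frame with `tag_id`, `sex`, `date`, `n_forays`.
#' @export
simulate_daily_counts <- function(config = sim_config(), seed = 1,
                                  n_males = config$n_males,
                                  n_females = config$n_females,
                                  days = config$deployment_days) {
  ids <- c(sprintf("M%02d", seq_len(n_males)),
           sprintf("F%02d", seq_len(n_females)))
  sexes <- c(rep("M", n_males), rep("F", n_females))
  set.seed(substream_seed(seed, "counts"))
  out <- lapply(seq_along(ids), function(i) {
    rate <- if (sexes[i] == "M") config$foray_rate[["male"]] else
      config$foray_rate[["female"]]
    data.frame(tag_id = ids[i], sex = sexes[i], date = seq_len(days) - 1L,
               n_forays = rpois(days, rate), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate provisioning observations with a prospecting trade-off
#'
#' Generates nestling-provisioning watches for each bird: the number of
#' feeds in a watch is Poisson with log mean
#' `log(baseline * hours) + beta_tradeoff * trailing_rate +
#' beta_brood_size * (brood_size - 2) + beta_brood_age * (brood_age - 9) +
#' sex_effect_male * male + bird_intercept`, where `trailing_rate` is the
#' bird's true foray rate over the `window_days` preceding the watch.
#'
#' @param daily_counts Per-bird-day foray counts ([truth_daily_counts()] or
#'   [simulate_daily_counts()]).
#' @param config A [sim_config()] (the `provisioning` element is used).
#' @param seed Integer seed.
#' @param n_obs_per_bird Number of observation days sampled per bird.
#' @return A data frame with `bird_id`, `sex`, `date`, `hours`, `feeds`,
#'   `brood_size`, `brood_age`, plus the generating `true_trailing_rate`.
#' @export
simulate_provisioning <- function(daily_counts, config = sim_config(),
                                  seed = 1, n_obs_per_bird = 3) {
  p <- config$provisioning
  dc <- as.data.frame(daily_counts)
  set.seed(substream_seed(seed, "provisioning"))
  out <- lapply(split(dc, dc$tag_id), function(b) {
    b <- b[order(b$date), ]
    w <- p$window_days
    cand <- b$date[b$date >= min(b$date) + w]
    if (!length(cand)) return(NULL)
    obs_days <- sort(sample(cand, min(n_obs_per_bird, length(cand))))
    trailing <- vapply(obs_days, function(d0)
      sum(b$n_forays[b$date >= d0 - w & b$date < d0]) / w, numeric(1))
    n <- length(obs_days)
    bs <- sample(1:3, n, replace = TRUE)
    ba <- sample(6:12, n, replace = TRUE)
    re <- rnorm(1, 0, p$bird_sd)
    hours <- rep(p$obs_hours, n)
    is_male <- b$sex[1] == "M"
    eta <- log(pmax(p$baseline_feeds_per_hour * hours, .Machine$double.xmin)) +
      p$beta_tradeoff * trailing + p$beta_brood_size * (bs - 2) +
      p$beta_brood_age * (ba - 9) + p$sex_effect_male * is_male + re
    feeds <- ifelse(hours > 0, rpois(n, exp(eta)), 0L)
    data.frame(bird_id = b$tag_id[1], sex = b$sex[1], date = obs_days,
               hours = hours, feeds = feeds, brood_size = bs, brood_age = ba,
               true_trailing_rate = trailing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bird_id = character(), sex = character(),
                      date = numeric(), hours = numeric(), feeds = integer(),
                      brood_size = integer(), brood_age = integer(),
                      true_trailing_rate = numeric())
  rownames(out) <- NULL
  out
}

#' Run the full simulate-localize-detect study
#'
#' End-to-end driver: builds the array, simulates movement and per-bird
#' detection logs, localizes each tag, detects its forays and aggregates
#' daily rates. Birds are processed one at a time so memory stays bounded at
#' realistic log volumes.
#'
#' @param sim_cfg A [sim_config()].
#' @param an_cfg An [analysis_config()].
#' @param seed Integer seed driving every simulation substream.
#' @param tags Optional subset of birds.
#' @param verbose Print per-bird progress.
#' @return A list with `array`, `movement` (including `truth` and
#'   `deployment`), `forays` (detected, all birds), `rates` (daily rates of
#'   non-censored forays) and `sex` (named vector).
#' @export
run_simulation_study <- function(sim_cfg = sim_config(),
                                 an_cfg = analysis_config(),
                                 seed = 1, tags = NULL, verbose = FALSE) {
  array <- make_array(sim_cfg, seed)
  movement <- simulate_movement(array, sim_cfg, seed)
  dep <- movement$deployment
  if (is.null(tags)) tags <- dep$tag_id
  forays <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    tg <- tags[i]
    logs <- simulate_logs(movement, seed, tags = tg)
    est <- localize_tag(logs, array, tg, an_cfg)
    forays[[i]] <- detect_forays(est, array, an_cfg)
    if (verbose)
      message(tg, ": ", nrow(logs), " logs, ",
              sum(!forays[[i]]$censored), " forays")
  }
  forays <- do.call(rbind, forays)
  rownames(forays) <- NULL
  dep_used <- dep[dep$tag_id %in% tags, , drop = FALSE]
  rates <- daily_rates(forays, dep_used, an_cfg)
  list(array = array, movement = movement, forays = forays, rates = rates,
       sex = setNames(dep$sex, dep$tag_id)[tags])
}

#' Summary statistics of a foray corpus
#'
#' The headline summaries of a detected foray corpus: number of
#' (non-censored) forays, mean/median duration, mean daily rate, and
#' mean/median/minimum round-trip distance.
#'
#' @param forays A foray table.
#' @param rates A daily-rate table ([daily_rates()]).
#' @return A list of class `foray_corpus`.
#' @export
foray_corpus <- function(forays, rates) {
  f <- forays[!forays$censored, , drop = FALSE]
  structure(list(
    n_forays = nrow(f),
    mean_duration_min = mean(f$duration_min),
    median_duration_min = median(f$duration_min),
    mean_daily_rate = mean(rates$n_forays),
    n_daily_measures = nrow(rates),
    n_birds = length(unique(rates$tag_id)),
    mean_round_trip_m = mean(f$round_trip_m),
    median_round_trip_m = median(f$round_trip_m),
    min_round_trip_m = if (nrow(f)) min(f$round_trip_m) else NA_real_
  ), class = "foray_corpus")
}

#' @export
print.foray_corpus <- function(x, ...) {
  cat(sprintf("Foray corpus: %d forays from %d birds (%d daily measures)\n",
              x$n_forays, x$n_birds, x$n_daily_measures))
  cat(sprintf("  duration: mean %.2f min, median %.2f min\n",
              x$mean_duration_min, x$median_duration_min))
  cat(sprintf("  daily rate: mean %.2f forays/day\n", x$mean_daily_rate))
  cat(sprintf("  round trip: mean %.1f m, median %.1f m, min %.1f m\n",
              x$mean_round_trip_m, x$median_round_trip_m, x$min_round_trip_m))
  invisible(x)
}
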