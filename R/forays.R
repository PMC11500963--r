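#' Detect extra-territorial forays in a location-estimate series
#'
#' Segments one tag's dense epoch series of best-estimate locations into
#' candidate non-home runs and retains those that qualify as extra-territorial
#' forays. A candidate run opens at a known non-home epoch and closes at the
#' next known *home* epoch; `unknown` epochs never break a run (animals far
#' from the array routinely go undetected mid-foray). A run qualifies as a
#' foray iff
#'
#' * the total known non-home time exceeds `config$min_nonhome_time`
#'   (strictly; `step * n_known_epochs > min_nonhome_time`), and
#' * the furthest assigned station during the run is further than
#'   `config$distance_threshold` from the home station (strictly).
#'
#' Foray duration is the time elapsed from the first non-home estimate to the
#' first subsequent home estimate; foray distance is the straight-line
#' distance from the home station to the furthest assigned station, and the
#' round-trip estimate is twice that. Runs not closed by a home estimate
#' before the data end, and runs that open before the animal was ever seen
#' home, are emitted with `censored = TRUE` (they are excluded from rate
#' summaries by default).
#'
#' @param estimates Location estimates for a single tag, as produced by
#'   [localize_tag()] (time-ordered, dense).
#' @param array A [station_array()].
#' @param config An [analysis_config()].
#' @param home One home station id; defaults to the tag's mapping in `array`.
#' @return A data frame with one row per foray: `tag_id`, `start_time`,
#'   `end_time` (`NA` for trailing censored runs), `duration_min`,
#'   `max_distance_m`, `round_trip_m`, `n_known_epochs`, `censored`.
#' @export
detect_forays <- function(estimates, array, config = analysis_config(),
                          home = NULL) {
  est <- as.data.frame(estimates)
  tags <- unique(as.character(est$tag_id))
  if (length(tags) > 1)
    stop("`estimates` must come from a single tag; got ", length(tags),
         call. = FALSE)
  empty <- data.frame(tag_id = character(), start_time = numeric(),
                      end_time = numeric(), duration_min = numeric(),
                      max_distance_m = numeric(), round_trip_m = numeric(),
                      n_known_epochs = integer(), censored = logical())
  if (!nrow(est)) return(empty)
  if (is.null(home)) home <- home_station(array, tags)
  est <- est[order(est$epoch_start), , drop = FALSE]

  known <- est$status == "known"
  at_home <- known & est$is_home
  nonhome <- known & !est$is_home
  if (!any(nonhome)) return(empty)

  ## run id = number of home epochs seen up to (and including) each epoch;
  ## all non-home known epochs sharing it belong to one candidate run
  h <- cumsum(at_home)
  home_times <- est$epoch_start[at_home]
  idx <- which(nonhome)
  run <- h[idx]

  dist_home <- station_distance(array, rep(home, length(idx)),
                                est$station_id[idx])
  start_time <- tapply(est$epoch_start[idx], run, min)
  n_epochs <- tapply(est$epoch_start[idx], run, length)
  max_dist <- tapply(dist_home, run, max)
  run_id <- as.numeric(names(start_time))

  ## the run with run id r closes at the (r+1)-th home epoch, if any
  end_time <- ifelse(run_id + 1 <= length(home_times),
                     home_times[run_id + 1], NA_real_)
  censored <- run_id == 0 | is.na(end_time)

  out <- data.frame(
    tag_id = tags,
    start_time = as.numeric(start_time),
    end_time = as.numeric(end_time),
    duration_min = (as.numeric(end_time) - as.numeric(start_time)) / 60,
    max_distance_m = as.numeric(max_dist),
    round_trip_m = 2 * as.numeric(max_dist),
    n_known_epochs = as.integer(n_epochs),
    censored = as.logical(censored),
    stringsAsFactors = FALSE
  )
  keep <- config$step * out$n_known_epochs > config$min_nonhome_time &
    out$max_distance_m > config$distance_threshold
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start_time), , drop = FALSE]
}

#' Detect forays for every tag
#'
#' @param estimates Location estimates for one or more tags
#'   ([localize_all()]).
#' @inheritParams detect_forays
#' @return Row-bound foray tables for all tags present.
#' @export
detect_forays_all <- function(estimates, array, config = analysis_config()) {
  tags <- unique(as.character(estimates$tag_id))
  out <- lapply(tags, function(tg)
    detect_forays(estimates[estimates$tag_id == tg, , drop = FALSE],
                  array, config))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## civil day index / hour of day from epoch seconds
civil_day <- function(t, config) floor((t + config$tz_offset_hours * 3600) / 86400)
civil_hour <- function(t, config) {
  floor((t + config$tz_offset_hours * 3600) / 3600) %% 24
}

#' Daily foray rates per tag
#'
#' Expands each tag's deployment interval into calendar days (civil time, see
#' `config$tz_offset_hours`) and counts forays per day; a foray is counted on
#' the day containing its `start_time`. Censored forays are excluded.
#'
#' @param forays A foray table ([detect_forays_all()]).
#' @param deployment Data frame with one row per tag: `tag_id`, `start`,
#'   `end` (deployment interval in seconds).
#' @param config An [analysis_config()].
#' @return A data frame with columns `tag_id`, `date` (integer civil day
#'   index), `n_forays`, `tracked`, one row per tag-day of deployment.
#' @export
daily_rates <- function(forays, deployment, config = analysis_config()) {
  deployment <- as.data.frame(deployment)
  stopifnot(all(c("tag_id", "start", "end") %in% names(deployment)))
  forays <- as.data.frame(forays)
  forays <- forays[!forays$censored, , drop = FALSE]
  if (nrow(forays)) {
    dep <- deployment[match(forays$tag_id, deployment$tag_id), ]
    if (anyNA(dep$tag_id))
      stop("foray from tag without deployment interval: ",
           paste(unique(forays$tag_id[is.na(dep$tag_id)]), collapse = ", "),
           call. = FALSE)
    outside <- forays$start_time < dep$start | forays$start_time > dep$end
    if (any(outside))
      stop(sum(outside), " foray(s) fall outside their tag's deployment",
           call. = FALSE)
  }
  days <- lapply(seq_len(nrow(deployment)), function(i) {
    data.frame(
      tag_id = deployment$tag_id[i],
      date = seq(civil_day(deployment$start[i], config),
                 civil_day(deployment$end[i], config)),
      stringsAsFactors = FALSE
    )
  })
  days <- do.call(rbind, days)
  if (nrow(forays)) {
    counts <- stats::aggregate(
      list(n_forays = forays$start_time),
      by = list(tag_id = forays$tag_id,
                date = civil_day(forays$start_time, config)),
      FUN = length
    )
    days <- merge(days, counts, by = c("tag_id", "date"), all.x = TRUE)
  } else {
    days$n_forays <- NA_integer_
  }
  days$n_forays[is.na(days$n_forays)] <- 0L
  days$tracked <- TRUE
  days <- days[order(days$tag_id, days$date), ]
  rownames(days) <- NULL
  days
}

#' Circadian profile of foray rates
#'
#' Mean hourly foray rate per bird per hour of the day: for each tag, forays
#' starting in each hour of day are counted and divided by the tag's number
#' of tracked days; the profile is the mean of these per-tag rates across
#' tags. Censored forays are excluded.
#'
#' @inheritParams daily_rates
#' @return A data frame with columns `hour` (0-23) and `rate` (forays per
#'   bird per tracked day starting in that hour).
#' @export
circadian_profile <- function(forays, deployment, config = analysis_config()) {
  deployment <- as.data.frame(deployment)
  forays <- as.data.frame(forays)
  forays <- forays[!forays$censored, , drop = FALSE]
  tracked_days <- civil_day(deployment$end, config) -
    civil_day(deployment$start, config) + 1
  names(tracked_days) <- deployment$tag_id
  per_tag <- vapply(deployment$tag_id, function(tg) {
    f <- forays[forays$tag_id == tg, , drop = FALSE]
    counts <- tabulate(civil_hour(f$start_time, config) + 1L, nbins = 24L)
    counts / tracked_days[[tg]]
  }, numeric(24))
  data.frame(hour = 0:23, rate = rowMeans(per_tag))
}

#' Sensitivity of foray detection to the distance threshold
#'
#' Re-runs foray detection over a grid of distance thresholds and reports the
#' total foray count and (optionally) the sex effect on daily foray rates at
#' each threshold. The sex effect is the male-vs-female log rate ratio from
#' a Poisson mixed model of per-bird-day foray counts with a bird-level
#' random intercept (fitted with \pkg{lme4}).
#'
#' @param estimates Location estimates for all tags ([localize_all()]).
#' @param array A [station_array()].
#' @param config An [analysis_config()]; its `distance_threshold` is replaced
#'   by each value of `thresholds` in turn.
#' @param thresholds Numeric vector of distance thresholds (m).
#' @param sex Named character vector (`"F"`/`"M"`) giving each tag's sex;
#'   when `NULL` the sex effect is not fitted.
#' @param deployment Deployment table (see [daily_rates()]); required for the
#'   sex effect.
#' @return A data frame with columns `threshold`, `total_forays`,
#'   `sex_effect`, `sex_effect_se`. Counts exclude censored runs. The effect
#'   is `NA` when fewer than two birds per sex are available.
#' @export
threshold_sensitivity <- function(estimates, array,
                                  config = analysis_config(),
                                  thresholds = seq(200, 350, by = 25),
                                  sex = NULL, deployment = NULL) {
  out <- lapply(thresholds, function(thr) {
    cfg <- config
    cfg$distance_threshold <- thr
    forays <- detect_forays_all(estimates, array, cfg)
    total <- sum(!forays$censored)
    eff <- c(NA_real_, NA_real_)
    if (!is.null(sex) && !is.null(deployment)) {
      rates <- daily_rates(forays, deployment, cfg)
      fit <- fit_sex_rate_model(rates, sex)
      if (!is.null(fit)) eff <- c(fit$estimate, fit$se)
    }
    data.frame(threshold = thr, total_forays = total,
               sex_effect = eff[1], sex_effect_se = eff[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sex effect on daily foray rates
#'
#' Poisson mixed model (log link) of per-bird-day foray counts on sex with a
#' bird-level random intercept; the reported estimate is the male-vs-female
#' log rate ratio.
#'
#' @param rates Daily rate table from [daily_rates()].
#' @param sex Named character vector (`"F"`/`"M"`) keyed by tag id.
#' @return A list with `estimate`, `se`, `rate_ratio` (exp of the estimate)
#'   and the fitted model (`fit`), or `NULL` when fewer than 2 birds per sex
#'   are present.
#' @export
fit_sex_rate_model <- function(rates, sex) {
  rates <- as.data.frame(rates)
  rates$sex <- factor(unname(sex[rates$tag_id]), levels = c("F", "M"))
  if (anyNA(rates$sex))
    stop("missing sex for tag(s): ",
         paste(unique(rates$tag_id[is.na(rates$sex)]), collapse = ", "),
         call. = FALSE)
  birds_per_sex <- tapply(rates$tag_id, rates$sex,
                          function(x) length(unique(x)))
  if (any(is.na(birds_per_sex)) || any(birds_per_sex < 2)) return(NULL)
  fit <- lme4::glmer(n_forays ~ sex + (1 | tag_id), data = rates,
                     family = stats::poisson())
  est <- lme4::fixef(fit)[["sexM"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[[2]]
  list(estimate = est, se = se, rate_ratio = exp(est), fit = fit)
}
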