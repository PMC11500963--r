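make_est <- function(pattern, array, step = 5) {
  # pattern: vector of "H" (known home), station id (known non-home),
  # or "U" (unknown)
  home <- array$home_of[["t1"]]
  station <- ifelse(pattern == "H", home,
                    ifelse(pattern == "U", NA_character_, pattern))
  data.frame(
    tag_id = "t1",
    epoch_start = (seq_along(pattern) - 1) * step,
    status = ifelse(pattern == "U", "unknown", "known"),
    station_id = station,
    mean_rssi = ifelse(is.na(station), NA_real_, -20),
    is_home = !is.na(station) & station == home
  )
}

ab_array <- function(dist_b = 300) {
  station_array(data.frame(station_id = c("A", "B"), x = c(0, dist_b),
                           y = c(0, 0)),
                home_of = c(t1 = "A"))
}

test_that("foray criteria reproduce the hand-traced reference cases", {
  cfg <- analysis_config()
  arr <- ab_array(300)

  # all home -> no forays
  expect_equal(nrow(detect_forays(make_est(rep("H", 10), arr), arr, cfg)), 0)

  # H,H,B,B,B,B,B,H: one foray; 5 non-home epochs (25 s > 15 s), 300 m away
  f <- detect_forays(make_est(c("H", "H", "B", "B", "B", "B", "B", "H"), arr),
                     arr, cfg)
  expect_equal(nrow(f), 1)
  expect_equal(f$n_known_epochs, 5L)
  expect_equal(f$max_distance_m, 300)
  expect_equal(f$round_trip_m, 600)
  expect_equal(f$start_time, 10)
  expect_equal(f$end_time, 35)
  expect_equal(f$duration_min, 25 / 60)
  expect_false(f$censored)

  # same pattern but B only 200 m away: fails the distance criterion
  arr200 <- ab_array(200)
  expect_equal(nrow(detect_forays(
    make_est(c("H", "H", "B", "B", "B", "B", "B", "H"), arr200),
    arr200, cfg)), 0)

  # H,B,B,B,H: 3 non-home epochs = 15 s, not > 15 s (strict)
  expect_equal(nrow(detect_forays(make_est(c("H", "B", "B", "B", "H"), arr),
                                  arr, cfg)), 0)

  # unknown epochs do not break a run: H,B,U...,B,H spans the gap
  pat <- c("H", "B", "B", rep("U", 20), "B", "B", "H")
  f2 <- detect_forays(make_est(pat, arr), arr, cfg)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$n_known_epochs, 4L)
  expect_equal(f2$start_time, 5)
  expect_equal(f2$end_time, (length(pat) - 1) * 5)
})

test_that("runs not closed by a home estimate are censored", {
  cfg <- analysis_config()
  arr <- ab_array(300)

  # trailing censored run: open at data end
  f <- detect_forays(make_est(c("H", "B", "B", "B", "B", "B"), arr), arr, cfg)
  expect_equal(nrow(f), 1)
  expect_true(f$censored)
  expect_true(is.na(f$end_time))

  # leading run (never seen home first) is censored even though it closes
  f2 <- detect_forays(make_est(c("B", "B", "B", "B", "B", "H"), arr), arr, cfg)
  expect_equal(nrow(f2), 1)
  expect_true(f2$censored)
  expect_equal(f2$end_time, 25)

  # mixed: censored runs do not swallow interior forays
  pat <- c("B", "B", "B", "B", "H", "B", "B", "B", "B", "H", "B", "B", "B", "B")
  f3 <- detect_forays(make_est(pat, arr), arr, cfg)
  expect_equal(nrow(f3), 3)
  expect_equal(f3$censored, c(TRUE, FALSE, TRUE))
})

test_that("daily rates count forays on their start day within deployment", {
  cfg <- analysis_config()
  arr <- ab_array(300)
  dep <- data.frame(tag_id = "t1", start = 0, end = 10 * 86400 - 1)

  # no forays -> 10 zero days
  r0 <- daily_rates(detect_forays(make_est(rep("H", 5), arr), arr, cfg),
                    dep, cfg)
  expect_equal(nrow(r0), 10)
  expect_true(all(r0$n_forays == 0))
  expect_true(all(r0$tracked))

  # 6 forays over 3 days (3, 2, 1) -> rates 3, 2, 1, mean 2 over those days
  starts <- c(0.1, 0.3, 0.5, 1.2, 1.4, 2.9) * 86400
  forays <- data.frame(tag_id = "t1", start_time = starts,
                       end_time = starts + 600, duration_min = 10,
                       max_distance_m = 300, round_trip_m = 600,
                       n_known_epochs = 10L, censored = FALSE)
  r <- daily_rates(forays, dep, cfg)
  expect_equal(r$n_forays[1:3], c(3L, 2L, 1L))
  expect_equal(mean(r$n_forays[1:3]), 2)
  expect_equal(sum(r$n_forays), 6L)

  # a foray starting at 23:59 counts on that day
  f_late <- forays[1, ]
  f_late$start_time <- 86340
  expect_equal(daily_rates(f_late, dep, cfg)$n_forays[1], 1L)

  # censored forays are excluded
  f_cens <- forays
  f_cens$censored <- TRUE
  expect_equal(sum(daily_rates(f_cens, dep, cfg)$n_forays), 0L)

  # forays outside deployment are a consistency error
  f_out <- forays[1, ]
  f_out$start_time <- 11 * 86400
  expect_error(daily_rates(f_out, dep, cfg), "outside")
})

test_that("circadian profiles average per-bird hourly rates and conserve counts", {
  cfg <- analysis_config()
  dep <- data.frame(tag_id = "t1", start = 0, end = 2 * 86400 - 1)

  # no forays -> 24 zeros
  empty <- data.frame(tag_id = character(), start_time = numeric(),
                      end_time = numeric(), duration_min = numeric(),
                      max_distance_m = numeric(), round_trip_m = numeric(),
                      n_known_epochs = integer(), censored = logical())
  p0 <- circadian_profile(empty, dep, cfg)
  expect_equal(p0$hour, 0:23)
  expect_equal(p0$rate, rep(0, 24))

  # one foray at 07:30 over 2 tracked days -> hour-7 value 0.5
  f <- data.frame(tag_id = "t1", start_time = 7.5 * 3600, end_time = 8 * 3600,
                  duration_min = 30, max_distance_m = 300, round_trip_m = 600,
                  n_known_epochs = 10L, censored = FALSE)
  p <- circadian_profile(f, dep, cfg)
  expect_equal(p$rate[p$hour == 7], 0.5)
  expect_equal(sum(p$rate), 0.5)

  # conservation: sum(profile) * tracked_days * n_birds = total forays
  dep2 <- data.frame(tag_id = c("t1", "t2"), start = 0, end = 4 * 86400 - 1)
  set.seed(3)
  starts <- runif(12, 0, 4 * 86400)
  f2 <- data.frame(tag_id = sample(c("t1", "t2"), 12, replace = TRUE),
                   start_time = starts, end_time = starts + 60,
                   duration_min = 1, max_distance_m = 300, round_trip_m = 600,
                   n_known_epochs = 10L, censored = FALSE)
  p2 <- circadian_profile(f2, dep2, cfg)
  expect_equal(sum(p2$rate) * 4 * 2, 12)
})

test_that("foray detection matches the brute-force scan on random series", {
  cfg <- analysis_config()
  set.seed(11)
  for (rep in 1:25) {
    arr <- random_test_array(n_stations = sample(4:8, 1))
    est <- random_estimates(arr, sample(50:400, 1))
    got <- detect_forays(est, arr, cfg)
    want <- oracle_forays(est, arr, arr$home_of[["t1"]], cfg)
    expect_same_forays(got, want)
    # every emitted foray satisfies the advertised invariants
    if (nrow(got)) {
      expect_true(all(got$max_distance_m > cfg$distance_threshold))
      expect_equal(got$round_trip_m, 2 * got$max_distance_m)
      expect_true(all(cfg$step * got$n_known_epochs > cfg$min_nonhome_time))
      ok <- !got$censored
      expect_true(all(got$end_time[ok] > got$start_time[ok]))
      # disjoint and time-ordered
      if (sum(ok) > 1) {
        f <- got[ok, ]
        expect_true(all(diff(f$start_time) > 0))
        expect_true(all(f$end_time[-nrow(f)] <= f$start_time[-1]))
      }
    }
  }
})

test_that("foray counts are monotone in both detection thresholds", {
  set.seed(23)
  arr <- random_test_array(n_stations = 8)
  est <- random_estimates(arr, 600)
  base <- analysis_config()
  counts_d <- vapply(seq(100, 500, by = 50), function(thr) {
    cfg <- base; cfg$distance_threshold <- thr
    sum(!detect_forays(est, arr, cfg)$censored)
  }, numeric(1))
  expect_true(all(diff(counts_d) <= 0))
  counts_t <- vapply(c(0, 5, 15, 30, 60), function(mt) {
    cfg <- base; cfg$min_nonhome_time <- mt
    sum(!detect_forays(est, arr, cfg)$censored)
  }, numeric(1))
  expect_true(all(diff(counts_t) <= 0))
})

test_that("threshold sensitivity reports counts and a recoverable sex effect", {
  # daily counts with a true 2x male rate, pushed through the count model
  scfg <- sim_config(n_males = 6, n_females = 6, deployment_days = 30,
                     foray_rate = c(female = 0.7, male = 1.4))
  dc <- simulate_daily_counts(scfg, seed = 5)
  rates <- data.frame(tag_id = dc$tag_id, date = dc$date,
                      n_forays = dc$n_forays, tracked = TRUE)
  sex <- setNames(dc$sex[!duplicated(dc$tag_id)],
                  dc$tag_id[!duplicated(dc$tag_id)])
  fit <- fit_sex_rate_model(rates, sex)
  expect_gt(fit$estimate, 0)
  expect_lt(abs(fit$estimate - log(2)), 3 * fit$se)
  # fewer than 2 birds per sex -> no effect
  one_m <- rates[rates$tag_id %in% c("M01", "F01", "F02"), ]
  expect_null(fit_sex_rate_model(one_m, sex))
})
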