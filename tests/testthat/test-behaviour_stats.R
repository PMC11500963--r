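test_that("the exact binomial sex test matches closed forms", {
  # the direct-observation counts: 115 male forays of 184
  res <- exact_binomial_sex_test(115, 184)
  expect_equal(res$proportion, 0.625)
  expect_lt(res$p_value, 0.001)

  # observed exactly at expectation
  expect_equal(exact_binomial_sex_test(92, 184)$p_value, 1.0)

  # all-male: p = 2 * 0.5^10
  expect_equal(exact_binomial_sex_test(10, 10)$p_value, 2 * 0.5^10,
               tolerance = 1e-12)

  # symmetry about p0 = 0.5
  for (k in c(0, 3, 7, 10)) {
    expect_equal(exact_binomial_sex_test(k, 10)$p_value,
                 exact_binomial_sex_test(10 - k, 10)$p_value,
                 tolerance = 1e-12)
  }

  # one-sided option
  expect_equal(exact_binomial_sex_test(10, 10, alternative = "greater")$p_value,
               0.5^10, tolerance = 1e-12)
  expect_error(exact_binomial_sex_test(5, 0), "n_total")
  expect_error(exact_binomial_sex_test(11, 10), "k_male")
})

fake_forays <- function(bird, day_counts, config = analysis_config()) {
  # day_counts named by day index (nearest day first is the caller's concern)
  rows <- lapply(names(day_counts), function(d) {
    n <- day_counts[[d]]
    if (n == 0) return(NULL)
    start <- as.numeric(d) * 86400 + seq_len(n) * 3600
    data.frame(tag_id = bird, start_time = start, end_time = start + 600,
               duration_min = 10, max_distance_m = 300, round_trip_m = 600,
               n_known_epochs = 10L, censored = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

test_that("trailing rates use the half-open preceding window", {
  cfg <- analysis_config()
  # counts 2, 1, 0 on days -1, -2, -3 relative to focal day 10
  f <- fake_forays("b1", c(`9` = 2, `8` = 1, `7` = 0))
  expect_equal(trailing_rate(f, "b1", 10, 3, cfg), 1.0)
  expect_equal(trailing_rate(f, "b1", 10, 1, cfg), 2.0)
  expect_equal(trailing_rate(f, "b1", 10, 2, cfg), 1.5)
  # the focal day itself is excluded
  f2 <- rbind(f, fake_forays("b1", c(`10` = 5)))
  expect_equal(trailing_rate(f2, "b1", 10, 3, cfg), 1.0)
  # no forays ever -> 0 for any window
  empty <- fake_forays("b1", c(`9` = 0))
  expect_equal(trailing_rate(data.frame(tag_id = character(),
                                        start_time = numeric(),
                                        censored = logical()),
                             "b1", 10, 5, cfg), 0)
  # translation invariance in the date frame
  f_shift <- f
  f_shift$start_time <- f_shift$start_time + 20 * 86400
  expect_equal(trailing_rate(f_shift, "b1", 30, 3, cfg),
               trailing_rate(f, "b1", 10, 3, cfg))
  # 1/window scaling for a fixed in-window count
  f3 <- fake_forays("b1", c(`9` = 4))
  expect_equal(trailing_rate(f3, "b1", 10, 2, cfg),
               2 * trailing_rate(f3, "b1", 10, 4, cfg))
})

test_that("trade-off tables join, exclude and drop as specified", {
  cfg <- analysis_config()
  dep <- data.frame(tag_id = c("b1", "b2"), start = 0, end = 20 * 86400 - 1)
  f <- rbind(fake_forays("b1", c(`4` = 2, `5` = 1)),
             fake_forays("b2", c(`6` = 3)))
  prov <- data.frame(bird_id = c("b1", "b2", "b1", "b3"),
                     sex = c("F", "M", "F", "M"),
                     date = c(6, 7, 1, 6), hours = 3, feeds = c(10, 4, 7, 2),
                     brood_size = 2, brood_age = 9)
  expect_message(
    expect_message(
      tab <- build_tradeoff_table(f, prov, dep, window_days = 3, config = cfg),
      "without"),
    "before deployment")
  # b3 untracked dropped; b1 day-1 window starts before deployment
  expect_equal(nrow(tab), 2)
  expect_equal(tab$bird_id, c("b1", "b2"))
  expect_equal(tab$trailing_prospecting_rate, c(3 / 3, 3 / 3))
  expect_equal(tab$window_days, c(3L, 3L))

  # empty provisioning -> empty output
  expect_equal(nrow(build_tradeoff_table(f, prov[0, ], dep, 3, cfg)), 0)
})

test_that("the trade-off model recovers a generating effect", {
  scfg <- sim_config(provisioning = list(beta_tradeoff = -0.3))
  dc <- simulate_daily_counts(scfg, seed = 21, n_males = 10, n_females = 10,
                              days = 30)
  obs <- simulate_provisioning(dc, scfg, seed = 21, n_obs_per_bird = 10)
  tab <- data.frame(bird_id = obs$bird_id, sex = obs$sex, date = obs$date,
                    provisioning_hours = obs$hours, feeds = obs$feeds,
                    trailing_prospecting_rate = obs$true_trailing_rate,
                    window_days = 3L, brood_size = obs$brood_size,
                    brood_age = obs$brood_age)
  fit <- fit_tradeoff_model(tab)
  expect_lt(fit$tradeoff$estimate, 0)
  expect_lt(abs(fit$tradeoff$estimate - (-0.3)), 3 * fit$tradeoff$se)
  expect_true(all(c("trailing_prospecting_rate", "sexM") %in%
                    fit$coefficients$term))

  # degenerate designs error out
  expect_error(fit_tradeoff_model(tab[tab$bird_id == "M01", ]), "2 birds")
  tab0 <- tab
  tab0$trailing_prospecting_rate <- 1
  expect_error(fit_tradeoff_model(tab0), "singular")
})

test_that("window sensitivity agrees with the single-window fit", {
  cfg <- analysis_config()
  scfg <- sim_config()
  dc <- simulate_daily_counts(scfg, seed = 33, n_males = 8, n_females = 8,
                              days = 25)
  obs <- simulate_provisioning(dc, scfg, seed = 33, n_obs_per_bird = 8)
  prov <- data.frame(bird_id = obs$bird_id, sex = obs$sex, date = obs$date,
                     hours = obs$hours, feeds = obs$feeds,
                     brood_size = obs$brood_size, brood_age = obs$brood_age)
  dep <- data.frame(tag_id = unique(dc$tag_id), start = 0,
                    end = 25 * 86400 - 1)
  # forays reconstructed from the generating daily counts
  f <- do.call(rbind, lapply(split(dc, dc$tag_id), function(b)
    fake_forays(b$tag_id[1], setNames(b$n_forays, b$date))))
  # lme4 may flag boundary (singular) random-intercept fits here; that is
  # expected at this size and irrelevant to the consistency being checked
  sens <- suppressWarnings(
    window_sensitivity(f, prov, dep, windows = c(2, 3, 5), config = cfg))
  expect_equal(nrow(sens), 3)
  single <- suppressWarnings(fit_tradeoff_model(
    build_tradeoff_table(f, prov, dep, 3, cfg)))
  expect_equal(sens$tradeoff_estimate[sens$window_days == 3],
               single$tradeoff$estimate)
  expect_equal(sens$tradeoff_se[sens$window_days == 3], single$tradeoff$se)
})
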