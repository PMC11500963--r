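#' Exact binomial test of a sex bias in observed forays
#'
#' Tests whether the proportion of directly observed forays conducted by
#' males deviates from an expected proportion (default 0.5, i.e. no sex
#' bias, appropriate for an even subordinate sex ratio). The two-sided
#' p-value is the conventional exact ("minlike") definition: the sum of the
#' probabilities of all outcomes no more likely than the observed count
#' (delegated to [stats::binom.test()]).
#'
#' @param k_male Number of forays by males.
#' @param n_total Total number of observed forays (>= 1).
#' @param p0 Null proportion.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list of class `sex_test` with `proportion` (`k_male / n_total`),
#'   `p_value`, `k_male`, `n_total`, `p0` and `alternative`.
#' @examples
#' exact_binomial_sex_test(115, 184)
#' @export
exact_binomial_sex_test <- function(k_male, n_total, p0 = 0.5,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (length(n_total) != 1 || n_total < 1)
    stop("`n_total` must be a single count >= 1", call. = FALSE)
  if (k_male < 0 || k_male > n_total)
    stop("`k_male` must lie in [0, n_total]", call. = FALSE)
  bt <- stats::binom.test(k_male, n_total, p = p0, alternative = alternative)
  structure(list(proportion = k_male / n_total,
                 p_value = bt$p.value,
                 k_male = as.integer(k_male), n_total = as.integer(n_total),
                 p0 = p0, alternative = alternative),
            class = "sex_test")
}

#' @export
print.sex_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial sex test: %d of %d forays by males (%.1f%%)\n",
    x$k_male, x$n_total, 100 * x$proportion))
  cat(sprintf("  H0: proportion = %g; %s p = %.4g\n",
              x$p0, x$alternative, x$p_value))
  invisible(x)
}

#' Trailing prospecting rate before a focal day
#'
#' Forays per day over the `window_days` civil days preceding (and
#' excluding) the focal day: forays whose start falls in the half-open day
#' window `[focal_date - window_days, focal_date)` divided by `window_days`.
#' Censored forays are excluded.
#'
#' @param forays A foray table.
#' @param bird_id Bird (tag) id.
#' @param focal_date Focal civil day index (see [daily_rates()]).
#' @param window_days Window length in days (>= 1).
#' @param config An [analysis_config()] (civil-time offset).
#' @return Trailing foray rate, forays/day.
#' @export
trailing_rate <- function(forays, bird_id, focal_date, window_days,
                          config = analysis_config()) {
  if (window_days < 1) stop("`window_days` must be >= 1", call. = FALSE)
  f <- forays[forays$tag_id == bird_id & !forays$censored, , drop = FALSE]
  if (!nrow(f)) return(0)
  day <- civil_day(f$start_time, config)
  sum(day >= focal_date - window_days & day < focal_date) / window_days
}

#' Pair provisioning observations with trailing prospecting rates
#'
#' Joins each provisioning watch to the focal bird's trailing prospecting
#' rate over the preceding `window_days`. Observations whose trailing
#' window extends before the bird's deployment are excluded (flagged with a
#' message), as are observations for birds with no tracking deployment.
#'
#' @param forays A foray table (all tracked birds).
#' @param provisioning Provisioning observations: `bird_id`, `date` (civil
#'   day index), `hours`, `feeds`, `brood_size`, `brood_age` and optionally
#'   `sex`.
#' @param deployment Deployment table (`tag_id`, `start`, `end` in seconds).
#' @param window_days Trailing window length, days.
#' @param config An [analysis_config()].
#' @return A data frame with one row per usable observation: `bird_id`,
#'   `sex` (if supplied), `date`, `provisioning_hours`, `feeds`,
#'   `trailing_prospecting_rate`, `window_days`, `brood_size`, `brood_age`.
#' @export
build_tradeoff_table <- function(forays, provisioning, deployment,
                                 window_days = 3,
                                 config = analysis_config()) {
  prov <- as.data.frame(provisioning)
  req <- c("bird_id", "date", "hours", "feeds", "brood_size", "brood_age")
  missing <- setdiff(req, names(prov))
  if (length(missing))
    stop("provisioning table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(prov)) {
    out <- data.frame(bird_id = character(), sex = character(),
                      date = numeric(), provisioning_hours = numeric(),
                      feeds = integer(), trailing_prospecting_rate = numeric(),
                      window_days = integer(), brood_size = numeric(),
                      brood_age = numeric())
    return(out)
  }
  deployment <- as.data.frame(deployment)
  untracked <- !(prov$bird_id %in% deployment$tag_id)
  if (any(untracked)) {
    message(sum(untracked), " provisioning row(s) dropped: bird(s) without ",
            "tracking data (",
            paste(unique(prov$bird_id[untracked]), collapse = ", "), ")")
    prov <- prov[!untracked, , drop = FALSE]
  }
  dep_first_day <- setNames(civil_day(deployment$start, config),
                            deployment$tag_id)
  window_ok <- prov$date - window_days >= dep_first_day[prov$bird_id]
  if (any(!window_ok)) {
    message(sum(!window_ok), " provisioning row(s) excluded: trailing window ",
            "extends before deployment")
    prov <- prov[window_ok, , drop = FALSE]
  }
  rate <- vapply(seq_len(nrow(prov)), function(i)
    trailing_rate(forays, prov$bird_id[i], prov$date[i], window_days, config),
    numeric(1))
  out <- data.frame(
    bird_id = prov$bird_id,
    sex = if ("sex" %in% names(prov)) prov$sex else NA_character_,
    date = prov$date,
    provisioning_hours = prov$hours,
    feeds = prov$feeds,
    trailing_prospecting_rate = rate,
    window_days = as.integer(window_days),
    brood_size = prov$brood_size,
    brood_age = prov$brood_age,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fit the prospecting-provisioning trade-off model
#'
#' Poisson mixed model (log link) of the number of feeds per provisioning
#' watch, with the log watch duration as an offset (so the model describes
#' the feed *rate*), fixed effects for the trailing prospecting rate plus
#' any of sex, brood age and brood size that vary in the data, and random
#' intercepts for bird (and social group when a `group_id` column is
#' present). Fitted with [lme4::glmer()].
#'
#' @param table A trade-off table from [build_tradeoff_table()].
#' @param nAGQ Integrator precision passed to [lme4::glmer()]; `0` is a
#'   faster approximate fit useful inside simulation loops.
#' @return An object of class `tradeoff_fit`: list with `coefficients` (data
#'   frame of `term`, `estimate`, `se`), `tradeoff` (the trailing-rate row)
#'   and the underlying `fit`.
#' @export
fit_tradeoff_model <- function(table, nAGQ = 1) {
  tab <- as.data.frame(table)
  if (length(unique(tab$bird_id)) < 2)
    stop("trade-off model needs >= 2 birds", call. = FALSE)
  if (!nrow(tab) || stats::var(tab$trailing_prospecting_rate) == 0)
    stop("no variation in trailing prospecting rate: design is singular",
         call. = FALSE)
  if (any(tab$provisioning_hours <= 0))
    stop("`provisioning_hours` must be > 0", call. = FALSE)
  terms <- "trailing_prospecting_rate"
  if ("sex" %in% names(tab) && length(unique(stats::na.omit(tab$sex))) > 1)
    terms <- c(terms, "sex")
  for (v in c("brood_age", "brood_size"))
    if (length(unique(tab[[v]])) > 1) terms <- c(terms, v)
  re <- "(1 | bird_id)"
  if ("group_id" %in% names(tab) && length(unique(tab$group_id)) > 1)
    re <- c(re, "(1 | group_id)")
  fml <- stats::as.formula(paste(
    "feeds ~", paste(c(terms, re), collapse = " + "),
    "+ offset(log(provisioning_hours))"))
  fit <- lme4::glmer(fml, data = tab, family = stats::poisson(), nAGQ = nAGQ)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 tradeoff = coefs[coefs$term == "trailing_prospecting_rate", ],
                 n_obs = nrow(tab), n_birds = length(unique(tab$bird_id)),
                 fit = fit),
            class = "tradeoff_fit")
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat(sprintf(
    "Prospecting-provisioning trade-off model (%d watches, %d birds)\n",
    x$n_obs, x$n_birds))
  cat(sprintf("  trailing-rate effect (log feeds/h per foray/day): %.3f (SE %.3f)\n",
              x$tradeoff$estimate, x$tradeoff$se))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.tradeoff_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.tradeoff_fit <- function(object, ...) summary(object$fit, ...)

#' Sensitivity of the trade-off estimate to the trailing-window length
#'
#' Rebuilds the trade-off table and refits the trade-off model for a range
#' of trailing-window lengths, collecting the trailing-rate coefficient and
#' its standard error for each.
#'
#' @inheritParams build_tradeoff_table
#' @param windows Integer vector of window lengths (days).
#' @param nAGQ Passed to [fit_tradeoff_model()].
#' @return A data frame with `window_days`, `tradeoff_estimate`,
#'   `tradeoff_se`, `n_obs`.
#' @export
window_sensitivity <- function(forays, provisioning, deployment,
                               windows = 1:7, config = analysis_config(),
                               nAGQ = 1) {
  out <- lapply(windows, function(w) {
    tab <- build_tradeoff_table(forays, provisioning, deployment, w, config)
    fit <- fit_tradeoff_model(tab, nAGQ = nAGQ)
    data.frame(window_days = w,
               tradeoff_estimate = fit$tradeoff$estimate,
               tradeoff_se = fit$tradeoff$se,
               n_obs = fit$n_obs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
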