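#' Fit the RSSI-distance calibration
#'
#' Fits the standard log-distance path-loss model
#' `rssi = intercept + slope * log10(distance)` to calibration-transect data
#' by ordinary least squares, and evaluates the fitted mean RSSI at the
#' reference distance to derive the home-override threshold used by the
#' location decision tree. `mode = "empirical-mean"` instead takes the raw
#' mean of RSSI observations near the reference distance (within
#' `reference_tol` metres), for deployments where a fitted curve is not
#' wanted.
#'
#' @param calibration Data frame with columns `distance` (m, > 0) and `rssi`.
#'   Additional columns (orientation, height, ...) are tolerated and ignored:
#'   the fit pools all observations.
#' @param reference_distance Distance (m) at which the threshold is
#'   evaluated.
#' @param mode `"fit"` (regression on log10 distance, the default) or
#'   `"empirical-mean"`.
#' @param reference_tol Half-width (m) of the distance band used by
#'   `"empirical-mean"`.
#' @return An object of class `rssi_model` with fields `intercept`, `slope`,
#'   `residual_sd`, `threshold_at_reference`, `reference_distance`, `mode`
#'   and `n`. A warning is issued when the fitted slope is not negative
#'   (signal should decay with distance).
#' @examples
#' d <- c(2, 10, 50, 100)
#' cal <- data.frame(distance = d, rssi = 20 - 25 * log10(d))
#' m <- fit_rssi_distance(cal)
#' m$threshold_at_reference  # 20 - 25*log10(50)
#' @export
fit_rssi_distance <- function(calibration, reference_distance = 50,
                              mode = c("fit", "empirical-mean"),
                              reference_tol = 5) {
  mode <- match.arg(mode)
  calibration <- as.data.frame(calibration)
  stopifnot(all(c("distance", "rssi") %in% names(calibration)))
  d <- as.numeric(calibration$distance)
  r <- as.numeric(calibration$rssi)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("calibration distances must be positive and finite", call. = FALSE)
  if (length(unique(d)) == 1)
    stop("all calibration distances are equal: fit is rank-deficient",
         call. = FALSE)
  if (length(unique(d)) < 3)
    stop("calibration needs at least 3 distinct distances", call. = FALSE)
  fit <- stats::lm(r ~ log10(d))
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  residual_sd <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  threshold <- if (mode == "fit") {
    intercept + slope * log10(reference_distance)
  } else {
    sel <- abs(d - reference_distance) <= reference_tol
    if (!any(sel))
      stop("no calibration observations within ", reference_tol, " m of the ",
           reference_distance, " m reference", call. = FALSE)
    mean(r[sel])
  }
  if (!is.na(slope) && slope >= 0)
    warning("fitted RSSI-distance slope is not negative; ",
            "calibration may be invalid", call. = FALSE)
  structure(
    list(intercept = intercept, slope = slope, residual_sd = residual_sd,
         threshold_at_reference = unname(threshold),
         reference_distance = reference_distance, mode = mode,
         n = length(d), fit = fit),
    class = "rssi_model"
  )
}

#' @export
print.rssi_model <- function(x, ...) {
  cat("RSSI-distance calibration (log-distance path-loss model)\n")
  cat(sprintf("  rssi = %.3f %+.3f * log10(distance_m)   [n = %d, residual sd %.3f]\n",
              x$intercept, x$slope, x$n, x$residual_sd))
  cat(sprintf("  threshold at %g m (%s): %.3f\n",
              x$reference_distance, x$mode, x$threshold_at_reference))
  invisible(x)
}

#' @export
coef.rssi_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict mean RSSI at given distances
#'
#' @param object An `rssi_model`.
#' @param distance Distances in metres (> 0).
#' @param ... Unused.
#' @return Predicted mean RSSI values.
#' @export
predict.rssi_model <- function(object, distance, ...) {
  stopifnot(all(distance > 0))
  object$intercept + object$slope * log10(distance)
}

#' Write / read an RSSI calibration model as JSON
#'
#' @param model An `rssi_model`.
#' @param path JSON file path.
#' @return `write_rssi_model()` returns `path` invisibly; `read_rssi_model()`
#'   an `rssi_model` (without the underlying `lm` fit).
#' @export
write_rssi_model <- function(model, path) {
  stopifnot(inherits(model, "rssi_model"))
  fields <- model[c("intercept", "slope", "residual_sd",
                    "threshold_at_reference", "reference_distance", "mode",
                    "n")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rssi_model
#' @export
read_rssi_model <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(c(fields, list(fit = NULL)), class = "rssi_model")
}

#' Empirical detection-probability curve
#'
#' Fraction of transmitted pulses that were received, per distance,
#' from calibration records of sent/received pulse counts. With
#' `monotone = TRUE` the curve is smoothed by decreasing isotonic regression
#' (pool-adjacent-violators, weighted by the number of pulses sent).
#'
#' @param records Data frame with columns `distance` (m), `n_sent` (> 0) and
#'   `n_received` (`<= n_sent`). Several rows per distance are pooled.
#' @param monotone Enforce a non-increasing curve.
#' @return A data frame with columns `distance` and `fraction`, sorted by
#'   distance.
#' @export
detection_probability_curve <- function(records, monotone = FALSE) {
  records <- as.data.frame(records)
  stopifnot(all(c("distance", "n_sent", "n_received") %in% names(records)))
  if (any(records$n_sent <= 0))
    stop("`n_sent` must be positive", call. = FALSE)
  if (any(records$n_received > records$n_sent | records$n_received < 0))
    stop("`n_received` must lie in [0, n_sent]", call. = FALSE)
  agg <- stats::aggregate(cbind(n_sent, n_received) ~ distance,
                          data = records, FUN = sum)
  agg <- agg[order(agg$distance), ]
  frac <- agg$n_received / agg$n_sent
  if (monotone && nrow(agg) > 1) {
    ## weighted PAVA via replication; decreasing fit = -isoreg(-y)
    w <- agg$n_sent
    x <- rep(seq_along(frac), w)
    y <- rep(-frac, w)
    iso <- stats::isoreg(x, y)
    frac <- -vapply(split(iso$yf, x), function(v) v[1], numeric(1))
  }
  data.frame(distance = agg$distance, fraction = unname(frac))
}
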