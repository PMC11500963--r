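#' Analysis configuration
#'
#' Bundles the tunable parameters of the localization and foray-detection
#' pipeline. The defaults are the deployed study settings: 15-s moving
#' windows advanced in 5-s steps, a 250-m foray distance threshold, a strict
#' `>15 s` minimum non-home time, and a home-override RSSI threshold of
#' -11.484 (the calibrated mean signal strength at the 50-m reference
#' distance).
#'
#' @param window_width Width of the moving RSSI-averaging window, seconds.
#' @param step Step between successive windows, seconds. Each location
#'   estimate accounts for the `step`-long epoch starting at its
#'   `epoch_start`, so epochs partition time even though windows overlap.
#' @param distance_threshold Minimum distance (m) from the home station to the
#'   furthest assigned station for a non-home run to qualify as a foray
#'   (strict inequality).
#' @param min_nonhome_time Minimum total known non-home time (s) for a foray
#'   (strict inequality; with 5-s epochs the default 15 requires at least 4
#'   known non-home epochs).
#' @param home_rssi_threshold RSSI above which the home station overrides a
#'   stronger non-home station in the location decision tree (strict
#'   inequality on the home station's window mean).
#' @param calibration_reference_distance Distance (m) at which the calibrated
#'   RSSI-distance model is evaluated to derive `home_rssi_threshold`.
#' @param tz_offset_hours Offset (h) added to log times before computing civil
#'   days and hours of day. Use 0 when times are already local (as in the
#'   bundled simulator), or the study-site UTC offset for UTC timestamps.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @seealso [sim_config()] for the simulator configuration,
#'   [read_analysis_config()] to materialize one from YAML/JSON.
#' @examples
#' cfg <- analysis_config()
#' cfg$distance_threshold
#' @export
analysis_config <- function(window_width = 15,
                            step = 5,
                            distance_threshold = 250,
                            min_nonhome_time = 15,
                            home_rssi_threshold = -11.484,
                            calibration_reference_distance = 50,
                            tz_offset_hours = 0) {
  cfg <- list(
    window_width = as.numeric(window_width),
    step = as.numeric(step),
    distance_threshold = as.numeric(distance_threshold),
    min_nonhome_time = as.numeric(min_nonhome_time),
    home_rssi_threshold = as.numeric(home_rssi_threshold),
    calibration_reference_distance = as.numeric(calibration_reference_distance),
    tz_offset_hours = as.numeric(tz_offset_hours)
  )
  if (!is.finite(cfg$step) || cfg$step <= 0)
    stop("`step` must be > 0", call. = FALSE)
  if (!is.finite(cfg$window_width) || cfg$window_width < cfg$step)
    stop("`window_width` must be >= `step`", call. = FALSE)
  if (!is.finite(cfg$distance_threshold) || cfg$distance_threshold <= 0)
    stop("`distance_threshold` must be > 0", call. = FALSE)
  if (!is.finite(cfg$min_nonhome_time) || cfg$min_nonhome_time < 0)
    stop("`min_nonhome_time` must be >= 0", call. = FALSE)
  if (!is.finite(cfg$home_rssi_threshold))
    stop("`home_rssi_threshold` must be finite", call. = FALSE)
  if (!is.finite(cfg$calibration_reference_distance) ||
      cfg$calibration_reference_distance <= 0)
    stop("`calibration_reference_distance` must be > 0", call. = FALSE)
  structure(cfg, class = c("analysis_config", "list"))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  cat(sprintf("  window %g s / step %g s\n", x$window_width, x$step))
  cat(sprintf("  foray criteria: > %g m from home, > %g s known non-home\n",
              x$distance_threshold, x$min_nonhome_time))
  cat(sprintf("  home-override RSSI threshold: %g (reference %g m)\n",
              x$home_rssi_threshold, x$calibration_reference_distance))
  cat(sprintf("  civil-time offset: %g h\n", x$tz_offset_hours))
  invisible(x)
}

#' Read or write an analysis configuration file
#'
#' Configurations are stored as flat YAML or JSON mappings with the field
#' names of [analysis_config()]; unknown fields are rejected, missing fields
#' take their defaults. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(analysis_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}

#' @param config An `analysis_config`.
#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

## Deterministic per-stage substream seeds derived from one master seed, so
## that individual simulation stages can be re-run in isolation.  Knuth-style
## multiplicative hash folded into the 32-bit signed range.
substream_seed <- function(seed, stage, unit = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.numeric(seed) * 2654435761 + stage_code * 97003 +
          as.numeric(unit) * 51803) %% 2147483647
  as.integer(x)
}
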