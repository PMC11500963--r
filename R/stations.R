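#' Receiver station array
#'
#' Represents the fixed receiver ("base station") array: planar station
#' coordinates in metres plus the mapping from each tag to its home station
#' (the receiver at the centre of the tagged animal's home territory).
#' Coordinates are projected planar metres; no geodesy is performed.
#'
#' @param stations A data frame with columns `station_id`, `x`, `y`
#'   (coordinates in metres).
#' @param home_of A named character vector mapping tag ids to station ids.
#' @return An object of class `station_array`.
#' @examples
#' arr <- station_array(
#'   data.frame(station_id = c("A", "B"), x = c(0, 300), y = c(0, 0)),
#'   home_of = c(tag1 = "A")
#' )
#' station_distance(arr, "A", "B")
#' @export
station_array <- function(stations, home_of = character()) {
  stations <- as.data.frame(stations)
  req <- c("station_id", "x", "y")
  if (!all(req %in% names(stations)))
    stop("`stations` must have columns station_id, x, y", call. = FALSE)
  stations$station_id <- as.character(stations$station_id)
  if (anyDuplicated(stations$station_id))
    stop("duplicate station id(s): ",
         paste(unique(stations$station_id[duplicated(stations$station_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(stations$x)) || !all(is.finite(stations$y)))
    stop("station coordinates must be finite numbers (metres)", call. = FALSE)
  home_of <- vapply(home_of, as.character, character(1))
  if (length(home_of) && is.null(names(home_of)))
    stop("`home_of` must be a named vector (names = tag ids)", call. = FALSE)
  missing_home <- setdiff(unique(home_of), stations$station_id)
  if (length(missing_home))
    stop("home station(s) not present in array: ",
         paste(missing_home, collapse = ", "), call. = FALSE)
  coords <- as.matrix(stations[, c("x", "y")])
  rownames(coords) <- stations$station_id
  structure(
    list(stations = stations[, req], home_of = home_of, coords = coords),
    class = "station_array"
  )
}

#' @export
print.station_array <- function(x, ...) {
  cat(sprintf("Station array: %d stations, %d tag home mappings\n",
              nrow(x$stations), length(x$home_of)))
  if (nrow(x$stations) >= 2)
    cat(sprintf("  mean nearest-neighbour spacing: %.1f m\n", nn_spacing(x)))
  invisible(x)
}

#' Euclidean distance between stations
#'
#' @param array A [station_array()].
#' @param a,b Station ids (vectorized, recycled).
#' @return Distance(s) in metres.
#' @export
station_distance <- function(array, a, b) {
  stopifnot(inherits(array, "station_array"))
  bad <- setdiff(unique(c(a, b)), rownames(array$coords))
  if (length(bad))
    stop("unknown station id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pa <- array$coords[a, , drop = FALSE]
  pb <- array$coords[b, , drop = FALSE]
  unname(sqrt(rowSums((pa - pb)^2)))
}

#' Home station of a tag
#'
#' @param array A [station_array()].
#' @param tag_id Tag id.
#' @return The home station id.
#' @export
home_station <- function(array, tag_id) {
  stopifnot(inherits(array, "station_array"))
  if (!tag_id %in% names(array$home_of))
    stop("no home station mapped for tag '", tag_id, "'", call. = FALSE)
  unname(array$home_of[[tag_id]])
}

#' Mean nearest-neighbour spacing of an array
#'
#' The mean over stations of the distance to the closest other station; the
#' summary used to characterise territory-centre spacing.
#'
#' @param array A [station_array()].
#' @return Mean nearest-neighbour distance in metres.
#' @export
nn_spacing <- function(array) {
  stopifnot(inherits(array, "station_array"))
  n <- nrow(array$coords)
  if (n < 2) stop("need at least 2 stations", call. = FALSE)
  d <- as.matrix(stats::dist(array$coords))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}
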