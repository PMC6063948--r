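#' Build a public-transport network from GTFS schedule tables
#'
#' Public-transport networks are modelled with stops as nodes and pairs of
#' successive stops of the same trip as edges. The travel time of one
#' traversal is measured between stop "midpoints": the time attached to a
#' stop is the arithmetic mean of its arrival and departure, and the edge
#' weight for one occurrence is the difference of the two midpoints, in
#' minutes. A stop pair served by several trips (or several times by one
#' trip) collapses to a single edge; the `collapse` policy chooses the mean
#' (typical travel time, the default) or the minimum (fastest service)
#' over the occurrences.
#'
#' @param stop_times a data.frame in GTFS `stop_times.txt` layout: columns
#'   `trip_id`, `stop_id`, `arrival_time`, `departure_time`,
#'   `stop_sequence`. Times are `HH:MM:SS` clock strings (hours may exceed
#'   24, as in schedule feeds) or numeric minutes.
#' @param stops optional data.frame in GTFS `stops.txt` layout (`stop_id`,
#'   `stop_lon`, `stop_lat`); when given, every referenced stop must be
#'   present and its coordinates are attached to the graph.
#' @param mode `"travel_time"` for midpoint travel-time weights in minutes,
#'   `"hop"` for all weights 1.
#' @param collapse `"mean"` or `"min"` over repeated traversals of a pair.
#' @return A [spatial_graph] with one node per distinct stop referenced.
#'   Trips whose stop times are not monotone are dropped with a warning.
#' @export
gtfs_to_network <- function(stop_times, stops = NULL,
                            mode = c("travel_time", "hop"),
                            collapse = c("mean", "min")) {
  mode <- match.arg(mode)
  collapse <- match.arg(collapse)
  need <- c("trip_id", "stop_id", "arrival_time", "departure_time",
            "stop_sequence")
  miss <- setdiff(need, names(stop_times))
  if (length(miss) > 0) {
    stop("stop_times is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  st <- stop_times
  st$trip_id <- as.character(st$trip_id)
  st$stop_id <- as.character(st$stop_id)
  st$arr <- parse_gtfs_minutes(st$arrival_time)
  st$dep <- parse_gtfs_minutes(st$departure_time)
  if (any(st$arr > st$dep)) {
    stop("arrival after departure at a stop", call. = FALSE)
  }
  if (!is.null(stops)) {
    unknown <- setdiff(unique(st$stop_id), as.character(stops$stop_id))
    if (length(unknown) > 0) {
      stop("stop ids absent from stops table: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  st <- st[order(st$trip_id, st$stop_sequence), , drop = FALSE]
  from <- character(0); to <- character(0); w <- numeric(0)
  dropped <- character(0)
  for (trip in split(st, st$trip_id)) {
    if (nrow(trip) < 2) next
    if (any(diff(trip$stop_sequence) <= 0)) {
      dropped <- c(dropped, trip$trip_id[1]); next
    }
    mid <- (trip$arr + trip$dep) / 2
    dt <- diff(mid)
    if (any(dt < 0)) {
      dropped <- c(dropped, trip$trip_id[1]); next
    }
    k <- nrow(trip)
    from <- c(from, trip$stop_id[-k])
    to <- c(to, trip$stop_id[-1])
    w <- c(w, dt)
  }
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped), " trip(s) with non-monotone times: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  nodes <- unique(st$stop_id)
  coords <- NULL
  if (!is.null(stops) &&
      all(c("stop_lon", "stop_lat") %in% names(stops))) {
    sl <- stops[match(nodes, as.character(stops$stop_id)), ]
    coords <- cbind(as.numeric(sl$stop_lon), as.numeric(sl$stop_lat))
    rownames(coords) <- nodes
  }
  if (mode == "hop") w <- rep(1, length(w))
  spatial_graph(cbind(from, to), weights = w, nodes = nodes, coords = coords,
                units = if (mode == "hop") "hops" else "minutes",
                collapse = collapse)
}

# "HH:MM:SS" (hours may exceed 24) or numeric minutes -> minutes
parse_gtfs_minutes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  parts <- regmatches(x, regexec("^\\s*(\\d+):([0-5]\\d):([0-5]\\d)\\s*$", x))
  bad <- lengths(parts) != 4
  if (any(bad)) {
    stop("unparseable GTFS time: ", x[bad][1], call. = FALSE)
  }
  h <- as.numeric(vapply(parts, `[`, "", 2L))
  m <- as.numeric(vapply(parts, `[`, "", 3L))
  s <- as.numeric(vapply(parts, `[`, "", 4L))
  (h * 3600 + m * 60 + s) / 60
}
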