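#' Ball volume around a node
#'
#' The ball B_n(r) is the set of nodes within shortest-path distance r of
#' the centre n: at most r traversed edges in an unweighted graph, or total
#' traversed weight at most r in a weighted one. The volume |B_n(r)| counts
#' the nodes in the ball, the centre included, so the volume at radius 0 is
#' exactly 1.
#'
#' @param g a [spatial_graph].
#' @param centre node id (character) of the ball centre.
#' @param r radius, >= 0, possibly a vector.
#' @param weight_mode how edge lengths are measured; see [volume_profile()].
#' @return Integer volume(s), one per radius.
#' @export
ball_volume <- function(g, centre, r, weight_mode = "native") {
  assert_spatial_graph(g)
  centre <- as.character(centre)
  if (!centre %in% node_ids(g)) {
    stop("unknown centre node: ", centre, call. = FALSE)
  }
  if (any(r < 0)) stop("radius must be non-negative", call. = FALSE)
  w <- resolve_weights(g, weight_mode)
  d <- igraph::distances(g$graph, v = centre, weights = w)[1, ]
  vapply(r, function(ri) sum(d <= ri), integer(1))
}

# Edge lengths under the chosen mode. NA tells igraph to ignore weights
# (plain BFS); "euclidean" replaces weights by coordinate distances;
# "native"/"network_distance"/"travel_time" use the stored weights (the
# latter two only relabel the units).
resolve_weights <- function(g, weight_mode) {
  weight_mode <- match.arg(weight_mode,
    c("native", "unweighted", "euclidean", "network_distance", "travel_time"))
  if (weight_mode == "unweighted") return(NA)
  if (weight_mode == "euclidean") {
    if (is.null(g$coords)) {
      stop("euclidean weight mode requires node coordinates", call. = FALSE)
    }
    el <- igraph::as_edgelist(g$graph, names = TRUE)
    if (nrow(el) == 0) return(numeric(0))
    return(sqrt(rowSums((g$coords[el[, 1], , drop = FALSE] -
                         g$coords[el[, 2], , drop = FALSE])^2)))
  }
  if (n_edges(g) == 0) return(numeric(0))
  igraph::E(g$graph)$weight
}

#' Ball-volume profile of a network
#'
#' Samples centres uniformly without replacement from the largest connected
#' component and aggregates, for every radius of a common grid, the
#' arithmetic mean and sample standard deviation of the ball volumes. One
#' shortest-path sweep per centre yields the volumes at all radii. The mean
#' volume is non-decreasing in the radius, equals 1 at radius 0, and
#' saturates at the component size, the ceiling drawn in volume plots.
#'
#' When `radii` is omitted the grid is chosen from a pilot sample of up to
#' 200 centres: integers `0:r_max` for unweighted (hop) radii, where r_max
#' is the largest pilot distance, and 64 evenly spaced values from 0 to the
#' 95% distance quantile for weighted radii.
#'
#' @param g a [spatial_graph].
#' @param radii optional increasing grid of radii (>= 0).
#' @param n_samples number of sampled centres; if the component is smaller,
#'   all its nodes are used.
#' @param seed integer seed for centre sampling.
#' @param weight_mode `"unweighted"` (hop radii), `"euclidean"` (coordinate
#'   distance weights), or `"native"`/`"network_distance"`/`"travel_time"`
#'   (stored weights).
#' @param centres optional explicit centre node ids (all must lie in the
#'   largest connected component); overrides sampling, e.g. for paired
#'   comparisons of nested models over identical centres.
#' @param chunk internal number of centres per shortest-path batch.
#' @return An object of class `volume_profile` with fields `radii`, `mean`,
#'   `sd`, `n_samples`, `network_size`, `weight_mode`, `units`.
#' @export
volume_profile <- function(g, radii = NULL, n_samples = 10000, seed = 1,
                           weight_mode = "native", centres = NULL,
                           chunk = 256L) {
  assert_spatial_graph(g)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  lcc <- largest_connected_component(g)
  w <- resolve_weights(lcc, weight_mode)
  nv <- n_nodes(lcc)
  if (is.null(centres)) {
    set.seed(as.integer(seed))
    centres <- if (n_samples >= nv) node_ids(lcc) else {
      sample(node_ids(lcc), n_samples)
    }
  } else {
    centres <- as.character(centres)
    if (!all(centres %in% node_ids(lcc))) {
      stop("all `centres` must lie in the largest connected component",
           call. = FALSE)
    }
  }
  if (is.null(radii)) {
    pilot <- centres[seq_len(min(200L, length(centres)))]
    Dp <- igraph::distances(lcc$graph, v = pilot, weights = w)
    unweighted <- identical(w, NA) ||
      (length(w) > 0 && all(w == 1)) || n_edges(lcc) == 0
    radii <- if (unweighted) {
      0:max(0, Dp[is.finite(Dp)])
    } else {
      rmax <- stats::quantile(Dp[is.finite(Dp)], 0.95, names = FALSE)
      if (rmax <= 0) rmax <- max(Dp[is.finite(Dp)], 1)
      seq(0, rmax, length.out = 64)
    }
  }
  radii <- as.numeric(radii)
  if (length(radii) == 0) stop("empty radius grid", call. = FALSE)
  if (any(radii < 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("`radii` must be strictly increasing and non-negative",
         call. = FALSE)
  }
  nr <- length(radii)
  s1 <- numeric(nr); s2 <- numeric(nr)
  for (start in seq(1L, length(centres), by = chunk)) {
    batch <- centres[start:min(start + chunk - 1L, length(centres))]
    D <- igraph::distances(lcc$graph, v = batch, weights = w)
    for (i in seq_len(nrow(D))) {
      vol <- cumsum(tabulate(
        findInterval(D[i, ], radii, left.open = TRUE) + 1L, nbins = nr))
      s1 <- s1 + vol
      s2 <- s2 + vol^2
    }
  }
  m <- length(centres)
  mu <- s1 / m
  sdv <- if (m > 1) sqrt(pmax(0, (s2 - m * mu^2) / (m - 1))) else
    rep(NA_real_, nr)
  structure(list(radii = radii, mean = mu, sd = sdv, n_samples = m,
                 network_size = nv, weight_mode = weight_mode,
                 units = if (identical(weight_mode, "unweighted")) "hops"
                         else lcc$units),
            class = "volume_profile")
}

#' @export
print.volume_profile <- function(x, ...) {
  cat(sprintf(paste0("<volume_profile> %d radii in [%g, %g] (%s), ",
                     "%d centres, network size %d\n"),
              length(x$radii), min(x$radii), max(x$radii), x$units,
              x$n_samples, x$network_size))
  invisible(x)
}

#' @export
as.data.frame.volume_profile <- function(x, ...) {
  data.frame(radius = x$radii, mean = x$mean, sd = x$sd, n = x$n_samples)
}

#' @export
plot.volume_profile <- function(x, log = "xy", ...) {
  keep <- if (grepl("x", log)) x$radii > 0 else rep(TRUE, length(x$radii))
  graphics::plot(x$radii[keep], x$mean[keep], log = log,
                 xlab = sprintf("radius (%s)", x$units),
                 ylab = "mean ball volume", pch = 16, cex = 0.6, ...)
  graphics::abline(h = x$network_size, lty = 3)
  invisible(x)
}

#' Per-centre volume deviations at one radius
#'
#' Returns the raw per-centre ball volumes at a single radius plus summary
#' statistics for diagnostic use (the deviation of volumes around their
#' mean is roughly normal for spatial model networks, and visibly
#' non-normal for some real networks). No pass/fail semantics.
#'
#' @inheritParams volume_profile
#' @param r single radius.
#' @return A list with `volumes`, `mean`, `sd`, `skewness`, and the
#'   Shapiro-Wilk statistic and p-value (`NA` when the sample is too small
#'   or degenerate).
#' @export
deviation_diagnostics <- function(g, r, n_samples = 10000, seed = 1,
                                  weight_mode = "native") {
  if (length(r) != 1 || r < 0) stop("`r` must be one non-negative radius",
                                    call. = FALSE)
  lcc <- largest_connected_component(g)
  w <- resolve_weights(lcc, weight_mode)
  set.seed(as.integer(seed))
  centres <- if (n_samples >= n_nodes(lcc)) node_ids(lcc) else {
    sample(node_ids(lcc), n_samples)
  }
  vols <- numeric(length(centres))
  for (start in seq(1L, length(centres), by = 256L)) {
    idx <- start:min(start + 255L, length(centres))
    D <- igraph::distances(lcc$graph, v = centres[idx], weights = w)
    vols[idx] <- rowSums(D <= r)
  }
  m <- mean(vols)
  s <- if (length(vols) > 1) stats::sd(vols) else NA_real_
  skew <- if (isTRUE(s > 0)) mean((vols - m)^3) / s^3 else NA_real_
  sh <- if (length(vols) >= 3 && isTRUE(s > 0)) {
    v <- if (length(vols) > 5000) vols[seq_len(5000)] else vols
    tryCatch(stats::shapiro.test(v), error = function(e) NULL)
  }
  list(volumes = vols, mean = m, sd = s, skewness = skew,
       shapiro_W = if (is.null(sh)) NA_real_ else unname(sh$statistic),
       shapiro_p = if (is.null(sh)) NA_real_ else sh$p.value)
}
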