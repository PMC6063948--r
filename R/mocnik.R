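#' Uniform random points in the unit hypercube
#'
#' @param n number of points (>= 1).
#' @param dim spatial dimension (>= 1).
#' @param seed integer seed; the same seed always yields the same points.
#' @return An `n` x `dim` numeric matrix with entries i.i.d. uniform on
#'   `[0, 1]`.
#' @export
sample_points <- function(n, dim = 2, seed = 1) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (dim < 1) stop("`dim` must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  matrix(stats::runif(n * dim), nrow = n, ncol = dim)
}

#' Directed edges of the Mocnik spatial-network model
#'
#' For every node n1, let delta(n1) be the Euclidean distance to its nearest
#' neighbour. A directed edge (n1, n2) is created if and only if
#' dist(n1, n2) <= rho * delta(n1). Each node therefore has out-degree at
#' least 1 (its nearest neighbour always qualifies), and rho > 1 controls
#' the density of the network. Distances exactly on the threshold are
#' included.
#'
#' The computation is exact (all pairs are considered) but chunked so that
#' the full n x n distance matrix is never materialised.
#'
#' @param points numeric matrix of point coordinates, one row per node;
#'   at least two distinct points.
#' @param rho density parameter, > 1.
#' @param chunk internal row-block size for the distance computation.
#' @return A two-column integer matrix of directed edges (from, to), as row
#'   indices into `points`.
#' @export
mocnik_edges <- function(points, rho, chunk = 512L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (!is.finite(rho) || rho <= 1) stop("`rho` must be > 1", call. = FALSE)
  rho2 <- rho^2
  out_from <- vector("list", ceiling(n / chunk))
  out_to <- vector("list", ceiling(n / chunk))
  ci <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared Euclidean distances from rows `idx` to all points, summed
    # per axis from exact coordinate differences (the expanded-square
    # formula cancels catastrophically for very close points)
    D2 <- matrix(0, length(idx), n)
    for (j in seq_len(ncol(points))) {
      dif <- outer(points[idx, j], points[, j], "-")
      D2 <- D2 + dif * dif
    }
    D2[cbind(seq_along(idx), idx)] <- Inf
    delta2 <- apply(D2, 1, min)
    if (any(delta2 == 0)) {
      stop("coincident points: nearest-neighbour distance is zero",
           call. = FALSE)
    }
    hits <- which(D2 <= rho2 * delta2, arr.ind = TRUE, useNames = FALSE)
    ci <- ci + 1L
    out_from[[ci]] <- idx[hits[, 1]]
    out_to[[ci]] <- hits[, 2]
  }
  cbind(from = unlist(out_from), to = unlist(out_to))
}

#' Build a Mocnik spatial network
#'
#' Samples `n` points uniformly in the unit hypercube, applies the
#' nearest-neighbour edge rule of [mocnik_edges()], and symmetrises to the
#' associated undirected graph (every analysis in the package works on the
#' undirected graph). All edge weights are 1 and the sampled coordinates are
#' stored on the graph.
#'
#' @param n number of nodes.
#' @param dim spatial dimension.
#' @param rho density parameter, > 1.
#' @param seed integer seed.
#' @return A [spatial_graph] with coordinates in `[0, 1]^dim`.
#' @export
build_mocnik <- function(n, dim = 2, rho = 1.8, seed = 1) {
  pts <- sample_points(n, dim, seed)
  ids <- as.character(seq_len(n))
  rownames(pts) <- ids
  e <- mocnik_edges(pts, rho)
  spatial_graph(cbind(ids[e[, 1]], ids[e[, 2]]), nodes = ids, coords = pts,
                units = "hops")
}

#' Specification of a hierarchical Mocnik model
#'
#' Describes nested node layers N_0 > N_1 > ... > N_l: the base layer N_0
#' holds all nodes, each higher layer is a strictly smaller nested subset,
#' and every layer is wired independently by the nearest-neighbour rule.
#' The optional `layer_weights` w_i turn the model into the weighted
#' variant, in which a layer-i edge carries weight w_i times its Euclidean
#' length (higher layers with small w_i model fast long-range services).
#'
#' @param layer_sizes strictly decreasing positive integers N_0 > ... > N_l,
#'   each at least 2.
#' @param rho density parameter, > 1.
#' @param dim spatial dimension.
#' @param layer_weights optional positive reals, one per layer.
#' @param seed integer seed governing both the point sample and the nested
#'   subset choices.
#' @return An object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(layer_sizes, rho = 1.8, dim = 2,
                           layer_weights = NULL, seed = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 1 || any(layer_sizes < 2)) {
    stop("every layer needs at least 2 nodes", call. = FALSE)
  }
  if (any(diff(layer_sizes) >= 0)) {
    stop("layer sizes must be strictly decreasing", call. = FALSE)
  }
  if (!is.finite(rho) || rho <= 1) stop("`rho` must be > 1", call. = FALSE)
  if (!is.null(layer_weights)) {
    if (length(layer_weights) != length(layer_sizes)) {
      stop("`layer_weights` must match `layer_sizes` in length",
           call. = FALSE)
    }
    if (any(!is.finite(layer_weights)) || any(layer_weights <= 0)) {
      stop("layer weights must be positive", call. = FALSE)
    }
  }
  structure(list(layer_sizes = layer_sizes, rho = rho, dim = as.integer(dim),
                 layer_weights = layer_weights, seed = as.integer(seed)),
            class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat(sprintf("<hierarchy_spec> layers N = {%s}, rho = %g, dim = %d%s\n",
              paste(x$layer_sizes, collapse = ", "), x$rho, x$dim,
              if (is.null(x$layer_weights)) "" else
                sprintf(", w = {%s}", paste(x$layer_weights, collapse = ", "))))
  invisible(x)
}

# shared machinery: sample base points, choose nested subsets, wire layers.
# The RNG stream is consumed in a fixed order (points first, then subsets
# top-down), so a spec extended by one more layer reuses exactly the same
# base points and lower-layer subsets as the shorter spec under the same
# seed -- the hierarchical edge set is then monotone in the set of layers.
hierarchical_layers <- function(spec) {
  pts <- sample_points(spec$layer_sizes[1], spec$dim, spec$seed)
  layers <- vector("list", length(spec$layer_sizes))
  layers[[1]] <- seq_len(spec$layer_sizes[1])
  for (i in seq_along(spec$layer_sizes)[-1]) {
    layers[[i]] <- sort(sample(layers[[i - 1]], spec$layer_sizes[i]))
  }
  list(points = pts, layers = layers)
}

build_hier_impl <- function(spec, weighted) {
  h <- hierarchical_layers(spec)
  ids <- as.character(seq_len(nrow(h$points)))
  rownames(h$points) <- ids
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_along(h$layers)) {
    sub <- h$layers[[i]]
    e <- mocnik_edges(h$points[sub, , drop = FALSE], spec$rho)
    gi <- cbind(sub[e[, 1]], sub[e[, 2]])
    from <- c(from, ids[gi[, 1]])
    to <- c(to, ids[gi[, 2]])
    if (weighted) {
      len <- sqrt(rowSums((h$points[gi[, 1], , drop = FALSE] -
                           h$points[gi[, 2], , drop = FALSE])^2))
      w <- c(w, spec$layer_weights[i] * len)
    }
  }
  if (!weighted) w <- rep(1, length(from))
  spatial_graph(cbind(from, to), weights = w, nodes = ids, coords = h$points,
                units = if (weighted) "length" else "hops",
                collapse = "min")
}

#' Build a (weighted) hierarchical Mocnik network
#'
#' `build_hierarchical()` wires every layer of the spec independently with
#' the nearest-neighbour rule, unions the layers' edges, and symmetrises;
#' all weights are 1. `build_weighted_hierarchical()` additionally requires
#' `layer_weights` and gives each layer-i edge the weight w_i times its
#' Euclidean length; a node pair connected in several layers keeps the
#' minimum weight (a traveller takes the fastest service available).
#'
#' Under a fixed seed, the base points and nested subsets are shared across
#' specs that extend one another, so adding a layer never removes an edge.
#'
#' @param spec a [hierarchy_spec()].
#' @return A [spatial_graph].
#' @export
build_hierarchical <- function(spec) {
  if (!inherits(spec, "hierarchy_spec")) {
    stop("`spec` must be a hierarchy_spec", call. = FALSE)
  }
  build_hier_impl(spec, weighted = FALSE)
}

#' @rdname build_hierarchical
#' @export
build_weighted_hierarchical <- function(spec) {
  if (!inherits(spec, "hierarchy_spec")) {
    stop("`spec` must be a hierarchy_spec", call. = FALSE)
  }
  if (is.null(spec$layer_weights)) {
    stop("weighted variant requires `layer_weights`", call. = FALSE)
  }
  build_hier_impl(spec, weighted = TRUE)
}
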