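#' Spatial graphs
#'
#' A `spatial_graph` is an undirected, simple (no self-loops, no parallel
#' edges), non-negatively weighted graph with optional node coordinates in
#' Euclidean space. It is the common container for every analysis in the
#' package: generated model networks, edge lists read from disk, and
#' transport networks built from schedule data all end up in this form.
#' Internally it wraps an [igraph::igraph] object; node identifiers are
#' opaque strings (integer-looking ids are not coerced), edge weights live
#' in the `weight` edge attribute, and coordinates, when present, are a
#' numeric matrix with one row per node.
#'
#' @param edges two-column character matrix (or data.frame) of node pairs;
#'   may have zero rows.
#' @param weights optional numeric vector of non-negative edge weights, one
#'   per row of `edges`; `NULL` means all weights 1 (unweighted).
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `edges`. Ids not in `edges` become isolated nodes.
#' @param coords optional numeric matrix of node coordinates with
#'   `length(nodes)` rows (rownames are matched to node ids when present,
#'   otherwise row order is taken to follow `nodes`).
#' @param units character tag recording the meaning of the weights
#'   (e.g. `"hops"`, `"minutes"`, `"length"`).
#' @param collapse how to merge parallel edges arising from the input:
#'   `"mean"` or `"min"` of their weights.
#'
#' @return An object of class `spatial_graph`: a list with elements
#'   `graph` (igraph), `coords` (matrix or `NULL`) and `units`.
#' @examples
#' g <- spatial_graph(cbind(c("a", "b"), c("b", "c")))
#' n_nodes(g)
#' @export
spatial_graph <- function(edges, weights = NULL, nodes = NULL, coords = NULL,
                          units = "hops", collapse = c("mean", "min")) {
  collapse <- match.arg(collapse)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && nrow(edges) > 0) {
    stop("`edges` must have two columns", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  if (is.null(weights)) {
    weights <- rep(1, nrow(edges))
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(edges)) {
    stop("`weights` must have one entry per edge", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("edge weights must be finite and non-negative", call. = FALSE)
  }
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
    keep <- edges[, 1] != edges[, 2]
    edges <- edges[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(edges)))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(unique(as.vector(edges)), nodes)
    if (length(missing) > 0) {
      stop("edge endpoints not in `nodes`: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  # collapse parallel edges (including reversed duplicates) by the policy
  if (nrow(edges) > 0) {
    key <- ifelse(edges[, 1] < edges[, 2],
                  paste(edges[, 1], edges[, 2], sep = "\r"),
                  paste(edges[, 2], edges[, 1], sep = "\r"))
    if (anyDuplicated(key)) {
      agg <- if (collapse == "mean") {
        tapply(weights, key, mean)
      } else {
        tapply(weights, key, min)
      }
      parts <- strsplit(names(agg), "\r", fixed = TRUE)
      edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
      weights <- as.numeric(agg)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)), weight = weights)
  }
  coords <- validate_coords(coords, nodes)
  structure(list(graph = g, coords = coords, units = units),
            class = "spatial_graph")
}

validate_coords <- function(coords, nodes) {
  if (is.null(coords)) return(NULL)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(nodes)) {
    stop("`coords` must have one row per node", call. = FALSE)
  }
  if (!is.null(rownames(coords))) {
    if (!setequal(rownames(coords), nodes)) {
      stop("coordinate rownames do not match node ids", call. = FALSE)
    }
    coords <- coords[nodes, , drop = FALSE]
  } else {
    rownames(coords) <- nodes
  }
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  coords
}

#' @rdname spatial_graph
#' @param x,g a `spatial_graph`.
#' @export
is_spatial_graph <- function(x) inherits(x, "spatial_graph")

assert_spatial_graph <- function(g) {
  if (!is_spatial_graph(g)) stop("expected a `spatial_graph`", call. = FALSE)
  invisible(g)
}

#' @rdname spatial_graph
#' @export
n_nodes <- function(g) {
  assert_spatial_graph(g)
  igraph::vcount(g$graph)
}

#' @rdname spatial_graph
#' @export
n_edges <- function(g) {
  assert_spatial_graph(g)
  igraph::ecount(g$graph)
}

#' @rdname spatial_graph
#' @export
node_ids <- function(g) {
  assert_spatial_graph(g)
  igraph::V(g$graph)$name
}

#' @rdname spatial_graph
#' @export
edge_table <- function(g) {
  assert_spatial_graph(g)
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  data.frame(from = el[, 1], to = el[, 2],
             weight = if (n_edges(g) > 0) igraph::E(g$graph)$weight else numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (weights: %s%s)\n",
              n_nodes(x), n_edges(x), x$units,
              if (is.null(x$coords)) ""
              else sprintf("; coords in R^%d", ncol(x$coords))))
  invisible(x)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component. Ties between equally
#' sized components are broken deterministically towards the component
#' containing the lexicographically smallest node id, so repeated runs on the
#' same graph always return the same subgraph. Volume profiles sample their
#' centres from this component, since every sampled ball must eventually
#' saturate at the component size.
#'
#' @param g a [spatial_graph].
#' @return A `spatial_graph` induced on the largest component (coordinates
#'   subset accordingly).
#' @export
largest_connected_component <- function(g) {
  assert_spatial_graph(g)
  if (n_nodes(g) == 0) stop("graph is empty", call. = FALSE)
  comp <- igraph::components(g$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest lexicographic node id among tied components
    reps <- vapply(best, function(ci) {
      min(igraph::V(g$graph)$name[comp$membership == ci])
    }, "")
    best <- best[order(reps)][1]
  }
  keep <- comp$membership == best
  induced_spatial(g, which(keep))
}

induced_spatial <- function(g, vidx) {
  sub <- igraph::induced_subgraph(g$graph, vidx)
  coords <- if (!is.null(g$coords)) {
    g$coords[igraph::V(sub)$name, , drop = FALSE]
  }
  structure(list(graph = sub, coords = coords, units = g$units),
            class = "spatial_graph")
}
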