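from_igraph <- function(ig, coords = NULL, units = "hops") {
  if (is.null(igraph::V(ig)$name)) {
    ig <- igraph::set_vertex_attr(ig, "name",
                                  value = as.character(seq_len(igraph::vcount(ig))))
  }
  el <- igraph::as_edgelist(ig, names = TRUE)
  spatial_graph(el, nodes = igraph::V(ig)$name, coords = coords,
                units = units)
}

#' Deterministic fixture graphs
#'
#' Small standard graphs used throughout the package's tests and examples:
#' square lattices and paths (with their natural coordinates), balanced
#' trees of constant branching factor, Erdos-Renyi G(n, p) graphs, and
#' complete graphs. All are unweighted [spatial_graph]s, reproducible from
#' the seed where randomness is involved.
#'
#' @param kind one of `"grid"`, `"tree"`, `"erdos_renyi"`, `"path"`,
#'   `"complete"`.
#' @param ... kind-specific parameters: `grid` takes `nrow` and `ncol`
#'   (default `ncol = nrow`), `tree` takes branching factor `b` and
#'   `depth`, `erdos_renyi` takes `n` and `p`, `path` and `complete`
#'   take `n`.
#' @param seed integer seed (used by `erdos_renyi`).
#' @return A [spatial_graph].
#' @examples
#' make_fixture("tree", b = 2, depth = 3)
#' @export
make_fixture <- function(kind = c("grid", "tree", "erdos_renyi", "path",
                                  "complete"),
                         ..., seed = 1) {
  kind <- match.arg(kind)
  p <- list(...)
  switch(kind,
    grid = {
      nr <- p$nrow %||% stop("grid needs `nrow`", call. = FALSE)
      nc <- p$ncol %||% nr
      if (nr < 1 || nc < 1) stop("grid dimensions must be >= 1", call. = FALSE)
      ig <- igraph::make_lattice(c(nr, nc))
      coords <- as.matrix(expand.grid(x = seq_len(nr), y = seq_len(nc)))
      from_igraph(ig, coords = coords)
    },
    tree = {
      b <- p$b %||% stop("tree needs branching factor `b`", call. = FALSE)
      depth <- p$depth %||% stop("tree needs `depth`", call. = FALSE)
      if (b < 1 || depth < 0) stop("invalid tree parameters", call. = FALSE)
      n <- if (b == 1) depth + 1 else (b^(depth + 1) - 1) / (b - 1)
      from_igraph(igraph::make_tree(n, children = b, mode = "undirected"))
    },
    erdos_renyi = {
      n <- p$n %||% stop("erdos_renyi needs `n`", call. = FALSE)
      pr <- p$p %||% stop("erdos_renyi needs `p`", call. = FALSE)
      if (pr < 0 || pr > 1) stop("`p` must be in [0, 1]", call. = FALSE)
      set.seed(as.integer(seed))
      from_igraph(igraph::sample_gnp(n, pr))
    },
    path = {
      n <- p$n %||% stop("path needs `n`", call. = FALSE)
      coords <- cbind(x = seq_len(n), y = rep(0, n))
      from_igraph(igraph::make_lattice(n), coords = coords)
    },
    complete = {
      n <- p$n %||% stop("complete needs `n`", call. = FALSE)
      from_igraph(igraph::make_full_graph(n))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
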