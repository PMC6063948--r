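#' Read a plain edge list
#'
#' Reads SNAP-style edge lists: one edge per line, two whitespace-separated
#' node ids, optionally a third weight column, `#` comment lines skipped.
#' Directed duplicates (`a b` and `b a`) and repeated pairs are collapsed to
#' a single undirected edge. Node ids are kept as opaque strings.
#'
#' @param path path to the edge-list file.
#' @param weighted if `TRUE`, a third numeric weight column is required.
#' @param coords_path optional path to a coordinate sidecar TSV with columns
#'   `node_id`, `x_1` ... `x_dim` (written by [write_graph()]); nodes listed
#'   only in the sidecar become isolated nodes.
#' @param collapse weight policy for repeated pairs, `"mean"` or `"min"`.
#' @param units units tag stored on the graph.
#' @return A [spatial_graph].
#' @export
read_edge_list <- function(path, weighted = FALSE, coords_path = NULL,
                           collapse = c("mean", "min"), units = "hops") {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  want <- if (weighted) 3L else 2L
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- idx[which(nf != want)[1]]
    stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                 bad, path, want, nf[nf != want][1]), call. = FALSE)
  }
  m <- matrix(as.character(unlist(fields)), ncol = want, byrow = TRUE)
  edges <- m[, 1:2, drop = FALSE]
  weights <- if (weighted) {
    w <- suppressWarnings(as.numeric(m[, 3]))
    if (any(is.na(w))) {
      bad <- idx[which(is.na(w))[1]]
      stop(sprintf("malformed line %d in %s: non-numeric weight", bad, path),
           call. = FALSE)
    }
    if (any(w < 0)) {
      bad <- idx[which(w < 0)[1]]
      stop(sprintf("invalid weight on line %d in %s: negative", bad, path),
           call. = FALSE)
    }
    w
  }
  nodes <- NULL
  coords <- NULL
  if (!is.null(coords_path)) {
    sc <- utils::read.table(coords_path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
    nodes <- union(unique(as.vector(edges)), sc$node_id)
    if (ncol(sc) > 1) {
      coords <- as.matrix(sc[, -1, drop = FALSE])
      storage.mode(coords) <- "double"
      rownames(coords) <- sc$node_id
      extra <- setdiff(nodes, sc$node_id)
      if (length(extra) > 0) {
        stop("nodes without coordinates in sidecar: ",
             paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
      }
      coords <- coords[nodes, , drop = FALSE]
    }
  }
  spatial_graph(edges, weights = weights, nodes = nodes, coords = coords,
                units = units, collapse = collapse)
}

#' Write a graph as an edge list plus coordinate sidecar
#'
#' Writes the edge list (`from to weight` per line) to `path` and a sidecar
#' TSV listing every node (with its coordinates when present) to
#' `coords_path`. The sidecar is always written so that isolated nodes
#' survive the round trip: `read_edge_list(path, weighted = TRUE,
#' coords_path)` reconstructs the graph.
#'
#' @param g a [spatial_graph].
#' @param path output edge-list path.
#' @param coords_path output sidecar path; default `paste0(path, ".nodes.tsv")`.
#' @return Invisibly, the two paths written.
#' @export
write_graph <- function(g, path, coords_path = paste0(path, ".nodes.tsv")) {
  assert_spatial_graph(g)
  et <- edge_table(g)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# netdim edge list: %d nodes, %d edges, units=%s",
                     n_nodes(g), n_edges(g), g$units), con)
  if (nrow(et) > 0) {
    writeLines(sprintf("%s %s %.17g", et$from, et$to, et$weight), con)
  }
  nodes <- node_ids(g)
  sc <- data.frame(node_id = nodes, stringsAsFactors = FALSE)
  if (!is.null(g$coords)) {
    cm <- g$coords[nodes, , drop = FALSE]
    colnames(cm) <- paste0("x_", seq_len(ncol(cm)))
    sc <- cbind(sc, as.data.frame(cm, row.names = NULL))
  }
  utils::write.table(sc, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, coords_path))
}
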