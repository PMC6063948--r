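# Independent oracles and small builders shared across the test files.
# These deliberately use naive algorithms (pairwise loops, Floyd-Warshall,
# exact segment-box clipping) so they share no code path with the package.

# brute-force nearest-neighbour edge rule over all ordered pairs
oracle_mocnik_edges <- function(points, rho) {
  n <- nrow(points)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((points[i, ] - points[j, ])^2))
    }
    thr <- rho * min(d)
    for (j in seq_len(n)) {
      if (j != i && d[j] <= thr) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  cbind(from = from, to = to)
}

edge_key <- function(e) sort(paste(e[, 1], e[, 2]))

# Floyd-Warshall all-pairs shortest paths on a spatial_graph
oracle_apsp <- function(g, unweighted = FALSE) {
  ids <- node_ids(g)
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  et <- edge_table(g)
  for (i in seq_len(nrow(et))) {
    w <- if (unweighted) 1 else et$weight[i]
    a <- et$from[i]; b <- et$to[i]
    D[a, b] <- min(D[a, b], w)
    D[b, a] <- min(D[b, a], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# random connected-ish weighted graph on <= nmax nodes
random_test_graph <- function(seed, nmax = 30, weighted = TRUE) {
  set.seed(seed)
  n <- sample(4:nmax, 1)
  ids <- as.character(seq_len(n))
  # tree backbone keeps the graph connected; extra random edges on top
  from <- ids[sapply(2:n, function(i) sample(seq_len(i - 1), 1))]
  to <- ids[2:n]
  extra <- max(0, round(n * 0.5))
  if (extra > 0) {
    a <- sample(ids, extra, replace = TRUE)
    b <- sample(ids, extra, replace = TRUE)
    keep <- a != b
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  w <- if (weighted) round(runif(length(from), 0.1, 5), 3) else
    rep(1, length(from))
  spatial_graph(cbind(from, to), weights = w, nodes = ids, collapse = "min",
                units = if (weighted) "length" else "hops")
}

# hand-constructed volume profile for fit tests
mk_profile <- function(r, mu, sd = rep(1, length(r)), n = 100,
                       network_size = 1e4, units = "hops") {
  structure(list(radii = as.numeric(r), mean = as.numeric(mu),
                 sd = as.numeric(sd), n_samples = n,
                 network_size = network_size, weight_mode = "unweighted",
                 units = units),
            class = "volume_profile")
}

# exact 2D segment-vs-half-open-box clipping oracle for the edges variant
oracle_edge_boxes <- function(coords, edges, side, offset) {
  seg_hits_box <- function(p, q, lo, hi) {
    # parametric clipping against [lo, hi) per axis (Liang-Barsky style,
    # closed box, then boundary points resolved by the floor convention)
    t0 <- 0; t1 <- 1
    d <- q - p
    for (ax in 1:2) {
      if (d[ax] == 0) {
        if (p[ax] < lo[ax] || p[ax] > hi[ax]) return(FALSE)
      } else {
        ta <- (lo[ax] - p[ax]) / d[ax]
        tb <- (hi[ax] - p[ax]) / d[ax]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) return(FALSE)
      }
    }
    # some point of the clipped sub-segment must fall in the half-open box
    for (t in unique(pmin(pmax(c(t0, (t0 + t1) / 2, t1), 0), 1))) {
      x <- p + t * d
      if (all(x >= lo) && all(x < hi)) return(TRUE)
    }
    FALSE
  }
  lo_all <- apply(coords, 2, min) - 2 * side
  hi_all <- apply(coords, 2, max) + 2 * side
  boxes <- character(0)
  i_rng <- floor((lo_all[1] - offset[1]) / side):ceiling((hi_all[1] - offset[1]) / side)
  j_rng <- floor((lo_all[2] - offset[2]) / side):ceiling((hi_all[2] - offset[2]) / side)
  for (e in seq_len(nrow(edges))) {
    p <- coords[edges[e, 1], ]; q <- coords[edges[e, 2], ]
    for (i in i_rng) {
      for (j in j_rng) {
        lo <- offset + side * c(i, j)
        hi <- lo + side
        if (seg_hits_box(p, q, lo, hi)) {
          boxes <- c(boxes, paste(i, j))
        }
      }
    }
  }
  length(unique(boxes))
}
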