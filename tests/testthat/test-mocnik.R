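test_that("uniform point sampling is seeded and well distributed", {
  expect_equal(dim(sample_points(1, dim = 3, seed = 1)), c(1, 3))
  expect_identical(sample_points(50, 2, seed = 7), sample_points(50, 2, seed = 7))
  expect_error(sample_points(0, 2, 1), "at least 1")
  expect_error(sample_points(5, 0, 1), "at least 1")

  p <- sample_points(1e4, 2, seed = 3)
  expect_true(all(p >= 0 & p <= 1))
  # CLT: per-axis mean within 0.5 +/- 0.02 (about 4 sigma, sd = 1/sqrt(12n))
  expect_true(all(abs(colMeans(p) - 0.5) < 0.02))
})

test_that("nearest-neighbour edge rule matches brute force and hand cases", {
  # collinear points at 0, 1, 3 with rho = 1.5: 0 and 1 are mutual
  # neighbours; 3 reaches both (delta = 2, threshold 3)
  pts <- matrix(c(0, 1, 3), ncol = 1)
  e <- mocnik_edges(pts, 1.5)
  expect_setequal(paste(e[, 1], e[, 2]), c("1 2", "2 1", "3 2", "3 1"))

  # two points are always mutual nearest neighbours
  e2 <- mocnik_edges(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), rho = 1.0001)
  expect_setequal(paste(e2[, 1], e2[, 2]), c("1 2", "2 1"))

  # brute-force equivalence on random point sets across dimensions,
  # including chunking across the block boundary
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    d <- sample(1:3, 1)
    pts <- matrix(runif(n * d), n, d)
    rho <- runif(1, 1.05, 2.5)
    got <- mocnik_edges(pts, rho, chunk = 7L)
    want <- oracle_mocnik_edges(pts, rho)
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }

  # threshold ties are included (rule uses <=): equidistant neighbours at
  # exactly rho * delta
  tie <- matrix(c(0, 1, 1.5), ncol = 1)
  et <- mocnik_edges(tie, rho = 1.5)  # node 1: delta 1, dist to node 3 = 1.5
  expect_true(any(et[, 1] == 1 & et[, 2] == 3))

  expect_error(mocnik_edges(matrix(0, 1, 2), 1.5), "at least 2")
  expect_error(mocnik_edges(matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE),
                            1.5), "coincident")
  expect_error(mocnik_edges(matrix(c(0, 1), 2, 1), rho = 1), "rho")
})

test_that("every node keeps out-degree at least one", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(runif(80), ncol = 2)
    e <- mocnik_edges(pts, runif(1, 1.01, 3))
    expect_setequal(unique(e[, 1]), seq_len(nrow(pts)))
  }
})

test_that("undirected model graphs are symmetrised and seeded", {
  g <- build_mocnik(2, dim = 2, rho = 1.5, seed = 1)
  expect_equal(n_edges(g), 1)

  g1 <- build_mocnik(300, 2, 1.8, seed = 5)
  g2 <- build_mocnik(300, 2, 1.8, seed = 5)
  expect_equal(edge_table(g1), edge_table(g2))
  expect_equal(g1$coords, g2$coords)

  # symmetrisation never exceeds the directed edge count
  pts <- sample_points(300, 2, seed = 5)
  expect_lte(n_edges(g1), nrow(mocnik_edges(pts, 1.8)))

  # edge growth is linear in n: edges/n stable across a size ladder
  ratios <- sapply(c(2500, 5000, 10000), function(n) {
    g <- build_mocnik(n, 2, 1.8, seed = 2)
    n_edges(g) / n_nodes(g)
  })
  expect_lt((max(ratios) - min(ratios)) / min(ratios), 0.15)
})

test_that("hierarchy specs validate their invariants", {
  expect_error(hierarchy_spec(c(100, 100)), "strictly decreasing")
  expect_error(hierarchy_spec(c(100, 1)), "at least 2")
  expect_error(hierarchy_spec(c(100, 10), rho = 1), "rho")
  expect_error(hierarchy_spec(c(100, 10), layer_weights = 1), "length")
  expect_error(hierarchy_spec(c(100, 10), layer_weights = c(1, -1)),
               "positive")
  expect_error(build_weighted_hierarchical(hierarchy_spec(c(100, 10))),
               "layer_weights")
})

test_that("a single-layer hierarchy degenerates to the plain model", {
  spec <- hierarchy_spec(500, rho = 1.8, dim = 2, seed = 9)
  gh <- build_hierarchical(spec)
  gm <- build_mocnik(500, 2, 1.8, seed = 9)
  expect_equal(edge_table(gh), edge_table(gm))
  expect_equal(gh$coords, gm$coords)
})

test_that("hierarchical edge sets are nested in the layer structure", {
  flat <- build_hierarchical(hierarchy_spec(c(600, 120), seed = 3))
  two <- build_hierarchical(hierarchy_spec(c(600, 120, 25), seed = 3))
  base <- build_mocnik(600, 2, 1.8, seed = 3)
  k_base <- edge_key(as.matrix(edge_table(base)[, 1:2]))
  k_flat <- edge_key(as.matrix(edge_table(flat)[, 1:2]))
  k_two <- edge_key(as.matrix(edge_table(two)[, 1:2]))
  expect_true(all(k_base %in% k_flat))
  expect_true(all(k_flat %in% k_two))
})

test_that("weighted layers multiply Euclidean length and merge by minimum", {
  # all weights 1, single layer: weights equal Euclidean edge lengths
  s1 <- hierarchy_spec(300, layer_weights = 1, seed = 2)
  gw <- build_weighted_hierarchical(s1)
  et <- edge_table(gw)
  len <- sqrt(rowSums((gw$coords[et$from, , drop = FALSE] -
                       gw$coords[et$to, , drop = FALSE])^2))
  expect_equal(et$weight, unname(len))

  # a pair present in two layers keeps w_i * length of the cheaper layer
  s2 <- hierarchy_spec(c(300, 80), layer_weights = c(1, 0.375), seed = 2)
  g2 <- build_weighted_hierarchical(s2)
  et2 <- edge_table(g2)
  len2 <- sqrt(rowSums((g2$coords[et2$from, , drop = FALSE] -
                        g2$coords[et2$to, , drop = FALSE])^2))
  ratio <- et2$weight / len2
  expect_true(all(abs(ratio - 1) < 1e-9 | abs(ratio - 0.375) < 1e-9))
  expect_true(any(abs(ratio - 0.375) < 1e-9))
})

test_that("weighted hierarchies only shorten shortest paths", {
  spec <- hierarchy_spec(c(250, 60, 15), layer_weights = c(1, 0.375, 0.25),
                         seed = 6)
  gh <- build_weighted_hierarchical(spec)
  gb <- build_weighted_hierarchical(hierarchy_spec(250, layer_weights = 1,
                                                   seed = 6))
  Dh <- igraph::distances(gh$graph, weights = igraph::E(gh$graph)$weight)
  Db <- igraph::distances(gb$graph, weights = igraph::E(gb$graph)$weight)
  ids <- node_ids(gb)
  expect_true(all(Dh[ids, ids] <= Db[ids, ids] + 1e-12))
})
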