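test_that("edge lists are parsed with duplicate and direction collapse", {
  f <- withr::local_tempfile(lines = c("# comment", "a b", "b c", "a b"))
  g <- read_edge_list(f)
  expect_equal(n_nodes(g), 3)
  expect_equal(n_edges(g), 2)

  fw <- withr::local_tempfile(lines = "a b 2.0")
  gw <- read_edge_list(fw, weighted = TRUE)
  expect_equal(edge_table(gw)$weight, 2.0)

  # a directed pair collapses to one undirected edge; oracle: the set of
  # unordered pairs in the file
  fd <- withr::local_tempfile(lines = c("a b", "b a", "b c"))
  gd <- read_edge_list(fd)
  pairs <- unique(edge_key(rbind(c("a", "b"), c("a", "b"), c("b", "c"))))
  expect_equal(sort(edge_key(as.matrix(edge_table(gd)[, 1:2]))), sort(pairs))
})

test_that("malformed edge lists fail with the offending line number", {
  f <- withr::local_tempfile(lines = c("a b", "c"))
  expect_error(read_edge_list(f), "line 2")
  fw <- withr::local_tempfile(lines = c("a b 1", "b c -2"))
  expect_error(read_edge_list(fw, weighted = TRUE), "negative")
  expect_error(read_edge_list(withr::local_tempfile(lines = "a b x"),
                              weighted = TRUE), "non-numeric")
})

test_that("parallel edges honour the collapse policy", {
  f <- withr::local_tempfile(lines = c("a b 2", "a b 4"))
  expect_equal(edge_table(read_edge_list(f, weighted = TRUE))$weight, 3)
  expect_equal(edge_table(read_edge_list(f, weighted = TRUE,
                                         collapse = "min"))$weight, 2)
})

test_that("largest connected component is deterministic and idempotent", {
  g <- spatial_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                           c("d", "e"), c("x", "y"), c("y", "z")))
  lcc <- largest_connected_component(g)
  expect_setequal(node_ids(lcc), c("a", "b", "c", "d", "e"))

  # connected graph: identity
  h <- spatial_graph(rbind(c("a", "b"), c("b", "c")))
  expect_setequal(node_ids(largest_connected_component(h)), node_ids(h))

  # tie between equal components -> lexicographically smallest node wins;
  # oracle: brute-force component enumeration via the edge list
  tie <- spatial_graph(rbind(c("m", "n"), c("n", "o"), c("o", "p"),
                             c("a", "b"), c("b", "c"), c("c", "d")))
  expect_setequal(node_ids(largest_connected_component(tie)),
                  c("a", "b", "c", "d"))

  # idempotence
  expect_equal(sort(node_ids(largest_connected_component(lcc))),
               sort(node_ids(lcc)))
  expect_error(largest_connected_component(
    spatial_graph(matrix(character(0), 0, 2))), "empty")
})

test_that("write/read round-trips graphs including isolated nodes", {
  # weighted triangle
  tri <- spatial_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                       weights = c(1, 2, 3))
  p <- withr::local_tempfile()
  write_graph(tri, p)
  tri2 <- read_edge_list(p, weighted = TRUE, coords_path = paste0(p, ".nodes.tsv"))
  expect_setequal(node_ids(tri2), node_ids(tri))
  et1 <- edge_table(tri); et2 <- edge_table(tri2)
  o1 <- order(et1$from, et1$to); o2 <- order(et2$from, et2$to)
  expect_equal(et1[o1, ], et2[o2, ], ignore_attr = TRUE)

  # two isolated nodes survive via the sidecar
  iso <- spatial_graph(matrix(character(0), 0, 2), nodes = c("u", "v"))
  p2 <- withr::local_tempfile()
  write_graph(iso, p2)
  iso2 <- read_edge_list(p2, weighted = TRUE,
                         coords_path = paste0(p2, ".nodes.tsv"))
  expect_setequal(node_ids(iso2), c("u", "v"))
  expect_equal(n_edges(iso2), 0)

  # property: random graphs with coordinates round-trip exactly
  for (seed in 1:5) {
    g <- random_test_graph(seed, nmax = 50)
    coords <- matrix(round(runif(2 * n_nodes(g)), 6), ncol = 2,
                     dimnames = list(node_ids(g), NULL))
    g$coords <- coords
    p3 <- withr::local_tempfile()
    write_graph(g, p3)
    g2 <- read_edge_list(p3, weighted = TRUE,
                         coords_path = paste0(p3, ".nodes.tsv"))
    expect_setequal(node_ids(g2), node_ids(g))
    canon <- function(et) {
      out <- data.frame(from = pmin(et$from, et$to),
                        to = pmax(et$from, et$to), weight = et$weight)
      out[order(out$from, out$to), ]
    }
    expect_equal(canon(edge_table(g)), canon(edge_table(g2)),
                 ignore_attr = TRUE)
    expect_equal(g2$coords[node_ids(g), ], coords[node_ids(g), ],
                 ignore_attr = TRUE)
  }
})

test_that("GTFS trips become midpoint-weighted stop-pair edges", {
  st <- data.frame(trip_id = "t1", stop_id = c("A", "B"),
                   arrival_time = c(0, 10), departure_time = c(2, 12),
                   stop_sequence = 1:2)
  g <- gtfs_to_network(st)
  expect_equal(edge_table(g)$weight, 10)  # midpoint(11) - midpoint(1)
  expect_equal(g$units, "minutes")

  # one-stop trip: a node, no edges
  g1 <- gtfs_to_network(data.frame(trip_id = "t", stop_id = "A",
                                   arrival_time = 0, departure_time = 0,
                                   stop_sequence = 1))
  expect_equal(n_nodes(g1), 1)
  expect_equal(n_edges(g1), 0)

  # two trips over the same pair: mean of the occurrence times (10, 14)
  st2 <- data.frame(trip_id = rep(c("t1", "t2"), each = 2),
                    stop_id = rep(c("A", "B"), 2),
                    arrival_time = c(0, 10, 100, 114),
                    departure_time = c(0, 10, 100, 114),
                    stop_sequence = c(1, 2, 1, 2))
  expect_equal(edge_table(gtfs_to_network(st2))$weight, 12)
  expect_equal(edge_table(gtfs_to_network(st2, collapse = "min"))$weight, 10)

  # hop mode
  expect_equal(edge_table(gtfs_to_network(st2, mode = "hop"))$weight, 1)
})

test_that("the bundled toy feed builds a weighted transport network", {
  st <- utils::read.csv(system.file("extdata", "toy_gtfs_stop_times.txt",
                                    package = "netdim"))
  stops <- utils::read.csv(system.file("extdata", "toy_gtfs_stops.txt",
                                       package = "netdim"))
  g <- gtfs_to_network(st, stops = stops)
  expect_equal(n_nodes(g), 6)
  expect_equal(g$units, "minutes")
  expect_false(is.null(g$coords))
  et <- edge_table(g)
  # A-B served by trips L1 (10 min) and L2 (11 min): mean 10.5
  ab <- et$weight[(et$from == "A" & et$to == "B") |
                    (et$from == "B" & et$to == "A")]
  expect_equal(ab, 10.5)
  # the express trip adds a direct A-D edge alongside the local chain
  expect_true(any((et$from == "A" & et$to == "D") |
                    (et$from == "D" & et$to == "A")))
})

test_that("GTFS parsing handles clock strings, bad trips and unknown stops", {
  st <- data.frame(trip_id = "t1", stop_id = c("A", "B"),
                   arrival_time = c("23:58:00", "25:08:00"),
                   departure_time = c("24:00:00", "25:10:00"),
                   stop_sequence = 1:2)
  expect_equal(edge_table(gtfs_to_network(st))$weight, 70)

  # non-monotone times: trip dropped with a warning, good trip kept
  st_bad <- rbind(st, data.frame(trip_id = "t2", stop_id = c("A", "B"),
                                 arrival_time = c("10:00:00", "09:00:00"),
                                 departure_time = c("10:00:00", "09:00:00"),
                                 stop_sequence = 1:2))
  expect_warning(g <- gtfs_to_network(st_bad), "non-monotone")
  expect_equal(n_edges(g), 1)

  stops <- data.frame(stop_id = "A", stop_lon = 0, stop_lat = 0)
  expect_error(gtfs_to_network(st, stops = stops), "absent")

  # node count equals distinct stops; edges bounded by successive pairs
  st3 <- data.frame(trip_id = rep("t", 4), stop_id = c("A", "B", "C", "A"),
                    arrival_time = c(0, 5, 10, 15),
                    departure_time = c(0, 5, 10, 15), stop_sequence = 1:4)
  g3 <- gtfs_to_network(st3)
  expect_equal(n_nodes(g3), 3)
  expect_lte(n_edges(g3), 3)
})
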