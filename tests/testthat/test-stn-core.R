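test_that("distance matrices are exact for euclidean geometry", {
  net <- mkNet(c("a", "b"), data.frame(t = 1, source = "a", target = "b",
                                       speed = 1),
               nSteps = 2, positions = rbind(c(0, 0), c(3, 4)))
  D <- distanceMatrix(net, 1)
  expect_equal(D[1, 2], 5)
  expect_equal(D[2, 1], 5)
  expect_equal(diag(D), c(0, 0))

  city <- twoCityFixture()
  expect_equal(distanceMatrix(city, 1)[1, 2], 150)
})

test_that("geodesic distances agree with an independent geodesic formula", {
  # London and Paris, (lat, lon); cross-checked against Karney's algorithm
  pos <- rbind(c(51.5074, -0.1278), c(48.8566, 2.3522))
  net <- stn(c("LON", "PAR"), pos,
             data.frame(t = 1, source = "LON", target = "PAR", speed = 100),
             observationWindow(2, 60), metricSpace("geodesic", 2, "m"))
  D <- distanceMatrix(net, 1)
  ref <- geosphere::distGeo(c(-0.1278, 51.5074), c(2.3522, 48.8566))
  expect_lt(abs(D[1, 2] - ref), 1)          # < 1 m over ~344 km
  expect_equal(D[1, 2], D[2, 1])
  expect_equal(diag(D), c(0, 0))
})

test_that("network save/load round-trips every field", {
  net <- randomGeometricSTN(10, 6, seed = 42)
  dir <- withr::local_tempdir()
  saveNetwork(net, dir)
  net2 <- loadNetwork(file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"),
                      file.path(dir, "meta.json"))
  expect_identical(nodeIds(net2), nodeIds(net))
  expect_equal(nodePositions(net2, 1), nodePositions(net, 1))
  expect_equal(obsWindow(net2)@tau, obsWindow(net)@tau)
  expect_equal(obsWindow(net2)@t1, obsWindow(net)@t1)
  expect_identical(nSnapshots(net2), nSnapshots(net))
  expect_identical(metricSpaceOf(net2)@kind, metricSpaceOf(net)@kind)
  for (i in seq_len(nSnapshots(net)))
    expect_equal(as.matrix(snapshotSpeeds(net2, i)),
                 as.matrix(snapshotSpeeds(net, i)))
})

test_that("round-trip preserves trajectories and infinite speeds", {
  net <- contactSTN(6, 5, p = 0.4, mobility = 50, seed = 7)
  dir <- withr::local_tempdir()
  saveNetwork(net, dir)
  net2 <- loadNetwork(file.path(dir, "trajectory.csv"),
                      file.path(dir, "edges.csv"),
                      file.path(dir, "meta.json"))
  for (i in seq_len(nSnapshots(net))) {
    expect_equal(nodePositions(net2, i), nodePositions(net, i))
    expect_equal(as.matrix(snapshotSpeeds(net2, i)),
                 as.matrix(snapshotSpeeds(net, i)))
  }
})

test_that("loader accepts the empty-edge case and enforces the contract", {
  dir <- withr::local_tempdir()
  writeLines(c("node_id,x,y", "a,0,0", "b,1,0", "c,2,0"),
             file.path(dir, "nodes.csv"))
  writeLines("t,source,target,speed", file.path(dir, "edges.csv"))
  jsonlite::write_json(list(tau = 1, T = 3, t1 = 0,
                            metric = list(kind = "euclidean", dimension = 2,
                                          units = "m")),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  net <- loadNetwork(file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"),
                     file.path(dir, "meta.json"))
  expect_equal(nNodes(net), 3)
  expect_equal(nrow(edgeTable(net)), 0)

  writeEdges <- function(lines) writeLines(c("t,source,target,speed", lines),
                                           file.path(dir, "edges.csv"))
  load1 <- function() loadNetwork(file.path(dir, "nodes.csv"),
                                  file.path(dir, "edges.csv"),
                                  file.path(dir, "meta.json"))
  writeEdges("1,a,z,5")
  expect_error(load1(), "unknown node")
  writeEdges("9,a,b,5")
  expect_error(load1(), "outside 1..T")
  writeEdges("1,a,b,-2")
  expect_error(load1(), "strictly positive")
  writeEdges(c("1,a,b,5", "1,a,b,7"))
  expect_error(load1(), "duplicate")
  writeEdges("1,a,b,inf")
  expect_true(is.infinite(as.matrix(snapshotSpeeds(load1(), 1))[1, 2]))
})

test_that("bidirectional loading expands undirected records", {
  dir <- withr::local_tempdir()
  writeLines(c("node_id,x,y", "a,0,0", "b,1,0"), file.path(dir, "nodes.csv"))
  writeLines(c("t,source,target,speed", "1,a,b,inf"),
             file.path(dir, "edges.csv"))
  jsonlite::write_json(list(tau = 1, T = 1, t1 = 0,
                            metric = list(kind = "euclidean", dimension = 2,
                                          units = "m")),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  net <- loadNetwork(file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"),
                     file.path(dir, "meta.json"), bidirectional = TRUE)
  S <- as.matrix(snapshotSpeeds(net, 1))
  expect_true(is.infinite(S[1, 2]) && is.infinite(S[2, 1]))
})

test_that("trajectory gaps are filled by last observation carried forward", {
  dir <- withr::local_tempdir()
  writeLines(c("t,node_id,x,y", "1,a,0,0", "3,a,5,0", "1,b,1,1"),
             file.path(dir, "traj.csv"))
  writeLines("t,source,target,speed", file.path(dir, "edges.csv"))
  jsonlite::write_json(list(tau = 1, T = 4, t1 = 0,
                            metric = list(kind = "euclidean", dimension = 2,
                                          units = "m")),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  net <- loadNetwork(file.path(dir, "traj.csv"), file.path(dir, "edges.csv"),
                     file.path(dir, "meta.json"))
  expect_equal(nodePositions(net, 2)["a", ], c(0, 0), ignore_attr = TRUE)
  expect_equal(nodePositions(net, 3)["a", ], c(5, 0), ignore_attr = TRUE)
  expect_equal(nodePositions(net, 4)["a", ], c(5, 0), ignore_attr = TRUE)
  expect_equal(nodePositions(net, 4)["b", ], c(1, 1), ignore_attr = TRUE)
})

test_that("aggregate graph is the union of snapshot edge sets", {
  edges <- data.frame(t = 7, source = "A", target = "B", speed = 1)
  net <- mkNet(c("A", "B", "C"), edges, nSteps = 100)
  g <- aggregateGraph(net)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_false(igraph::are_adjacent(g, "B", "A"))
  expect_equal(igraph::graph_attr(g, "nEdges"), 1)
  expect_equal(igraph::graph_attr(g, "density"), 1 / (3 * 2))

  # union semantics against a brute-force recount on a random network,
  # invariant to snapshot order
  net <- randomGeometricSTN(10, 8, seed = 11)
  ed <- edgeTable(net)
  union1 <- unique(ed[, c("source", "target")])
  g2 <- aggregateGraph(net)
  expect_equal(igraph::graph_attr(g2, "nEdges"), nrow(union1))
  perm <- sample(nSnapshots(net))
  netPerm <- stn(nodeIds(net), nodePositions(net, 1), net@snapshots[perm],
                 obsWindow(net), metricSpaceOf(net))
  gPerm <- aggregateGraph(netPerm)
  expect_equal(as.matrix(igraph::as_adjacency_matrix(gPerm)),
               as.matrix(igraph::as_adjacency_matrix(g2)))
})

test_that("validation flags co-location and temporal under-sampling", {
  expect_error(stn(c("a", "b"), rbind(c(0, 0), c(0, 0)),
                   data.frame(t = integer(0), source = character(0),
                              target = character(0), speed = numeric(0)),
                   observationWindow(2, 1)), NA)
  netBad <- stn(c("a", "b"), rbind(c(0, 0), c(0, 0)),
                data.frame(t = integer(0), source = character(0),
                           target = character(0), speed = numeric(0)),
                observationWindow(2, 1))
  rep <- validateNetwork(netBad)
  expect_false(rep@pass)
  expect_true("colocated_nodes" %in% rep@findings$code)

  # an edge covering its distance in tau/2 under-samples the dynamics
  fast <- mkNet(c("a", "b"),
                data.frame(t = 1, source = "a", target = "b", speed = 2),
                nSteps = 2, tau = 1)
  repFast <- validateNetwork(fast)
  expect_true(repFast@pass)
  expect_true("undersampled" %in% repFast@findings$code)

  # two-city fixture: min direct duration is 3 tau -> clean pass
  repCity <- validateNetwork(twoCityFixture())
  expect_true(repCity@pass)
  expect_equal(nrow(repCity@findings), 0)
})

test_that("constructor rejects malformed inputs", {
  expect_error(mkNet(c("a", "b"),
                     data.frame(t = 1, source = "a", target = "a", speed = 1),
                     nSteps = 2), "self-edges")
  expect_error(mkNet(c("a", "b"),
                     data.frame(t = 1, source = "a", target = "b", speed = 0),
                     nSteps = 2), "strictly positive")
})
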