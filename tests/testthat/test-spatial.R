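test_that("adjacency construction matches hand-enumerable geometry", {
  # three non-collinear points triangulate to the single triangle
  tri <- data.frame(region_id = c("a", "b", "c"), x = c(0, 1, 0),
                    y = c(0, 0, 1), phenotype = 1)
  g <- buildAdjacency(tri, method = "delaunay")
  expect_equal(nrow(graphEdges(g)), 3L)

  # radius = Inf on 4 collinear points gives the complete graph K4
  line <- data.frame(region_id = paste0("p", 1:4), x = 1:4, y = 0,
                     phenotype = 1)
  k4 <- buildAdjacency(line, method = "radius", radius = Inf)
  expect_equal(nrow(graphEdges(k4)), 6L)

  # collinear sets fall back from delaunay to knn(k = 2) with a warning
  expect_warning(fb <- buildAdjacency(line, method = "delaunay"),
                 "collinear")
  expect_equal(fb@method, "knn")

  # knn k = 1 on two separated dumbbells: exactly the two short edges
  db <- data.frame(region_id = paste0("p", 1:4),
                   x = c(0, 1, 10, 11), y = 0, phenotype = 1)
  k1 <- buildAdjacency(db, method = "knn", k = 1)
  expect_setequal(edgeKey(k1), c("p1 p2", "p3 p4"))

  # explicit edges: unknown IDs and self-edges rejected
  tre <- toyExperiment()
  ex <- buildAdjacency(tre, method = "explicit",
                       edgeList = data.frame(region_a = c("r1", "r2"),
                                             region_b = c("r2", "r3")))
  expect_setequal(edgeKey(ex), c("r1 r2", "r2 r3"))
  expect_error(buildAdjacency(tre, method = "explicit",
                              edgeList = data.frame(region_a = "r1",
                                                    region_b = "zz")),
               "unknown region")
  expect_error(buildAdjacency(tre, method = "explicit",
                              edgeList = data.frame(region_a = "r1",
                                                    region_b = "r1")),
               "self-edge")

  # adjacency lists round-trip
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeAdjacencyList(ex, tmp)
  back <- readAdjacencyList(tmp)
  expect_equal(nrow(back), 2L)
  ex2 <- buildAdjacency(tre, method = "explicit", edgeList = back)
  expect_identical(edgeKey(ex2), edgeKey(ex))
})

test_that("Delaunay edges agree with the empty-circumcircle oracle and
           contain the minimum spanning tree", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    xy <- cbind(runif(n), runif(n))
    regions <- data.frame(region_id = sprintf("v%02d", 1:n),
                          x = xy[, 1], y = xy[, 2], phenotype = 1)
    del <- buildAdjacency(regions, method = "delaunay")
    got <- edgeKey(del)
    oracle <- bruteDelaunayEdges(xy)
    want <- sort(paste(regions$region_id[pmin(oracle[, 1], oracle[, 2])],
                       regions$region_id[pmax(oracle[, 1], oracle[, 2])]))
    expect_identical(got, want)

    # MST (on the complete distance graph) is a subgraph of the Delaunay
    dmat <- as.matrix(dist(xy))
    full <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE)
    mst <- igraph::mst(full)
    me <- igraph::as_edgelist(mst)
    mstKey <- paste(
      regions$region_id[pmin(as.integer(me[, 1]), as.integer(me[, 2]))],
      regions$region_id[pmax(as.integer(me[, 1]), as.integer(me[, 2]))])
    expect_true(all(mstKey %in% got))
  }
})

test_that("ordered pairs double every edge and attach phenotypes", {
  tre <- toyExperiment()
  tri <- buildAdjacency(tre, method = "explicit",
                        edgeList = data.frame(
                          region_a = c("r1", "r2", "r1"),
                          region_b = c("r2", "r3", "r3")))
  pairs <- makeOrderedPairs(tri, tre)
  expect_equal(nrow(pairs), 6L)

  # reversing all rows maps the table onto itself
  fwd <- paste(pairs$target, pairs$partner)
  rev <- paste(pairs$partner, pairs$target)
  expect_setequal(fwd, rev)

  # single-edge content
  one <- buildAdjacency(tre, method = "explicit",
                        edgeList = data.frame(region_a = "r1",
                                              region_b = "r2"))
  p1 <- makeOrderedPairs(one, tre)
  expect_equal(p1$y_target, c(2, 3))
  expect_equal(p1$y_partner, c(3, 2))
  expect_equal(p1$distance[1], p1$distance[2])

  # single mode halves the table
  expect_equal(nrow(makeOrderedPairs(tri, tre, mode = "single")), 3L)

  # empty edge set gives an empty table
  empty <- buildAdjacency(tre, method = "radius", radius = 1e-6)
  expect_equal(nrow(makeOrderedPairs(empty, tre)), 0L)
})

test_that("derivative traits obey the product/ratio/inverse definitions", {
  regions <- data.frame(region_id = c("A", "B"), x = c(0, 2), y = 0,
                        phenotype = c(2, 3))
  g <- matrix(c(0L, 1L), 1, 2, dimnames = list("L1", c("A", "B")))
  tre <- suppressWarnings(TumorRegionExperiment(g, regions))
  graph <- buildAdjacency(tre, method = "radius", radius = 10)
  pairs <- makeOrderedPairs(graph, tre)

  coop <- deriveTrait(pairs, "cooperation", weightByDistance = TRUE)
  expect_equal(coop$z, c(6, 6))
  expect_equal(coop$z_weighted, c(3, 3))

  alt <- deriveTrait(pairs, "altruism", weightByDistance = FALSE)
  expect_equal(sort(alt$z), sort(c(2 / 3, 3 / 2)))
  expect_equal(alt$z[1] * alt$z[2], 1)

  comp <- deriveTrait(pairs, "competition", weightByDistance = FALSE)
  expect_equal(comp$z, 1 / deriveTrait(pairs, "cooperation",
                                       weightByDistance = FALSE)$z)
  expect_equal(comp$z[1], 1 / 6)

  # nonpositive phenotypes break ratio/inverse traits, naming the region
  regions$phenotype[1] <- -1
  treNeg <- suppressWarnings(TumorRegionExperiment(g, regions))
  pNeg <- makeOrderedPairs(buildAdjacency(treNeg, method = "radius",
                                          radius = 10), treNeg)
  expect_error(deriveTrait(pNeg, "altruism"), "A")
  expect_equal(deriveTrait(pNeg, "cooperation")$z, c(-3, -3))
})

test_that("derivative-trait identities hold on randomized datasets", {
  for (seed in 1:5) {
    sim <- simulateTumor(simulationConfig(nRegions = 15, nLoci = 10,
                                          seed = 700 + seed))
    tre <- experiment(sim)
    pairs <- makeOrderedPairs(adjacency(sim), tre)
    coop <- deriveTrait(pairs, "cooperation", weightByDistance = FALSE)
    comp <- deriveTrait(pairs, "competition", weightByDistance = FALSE)
    alt <- deriveTrait(pairs, "altruism", weightByDistance = FALSE)
    expect_equal(comp$z, 1 / coop$z)
    key <- paste(pairs$target, pairs$partner)
    revKey <- paste(pairs$partner, pairs$target)
    recip <- alt$z * alt$z[match(key, revKey)]
    expect_equal(recip, rep(1, length(recip)), tolerance = 1e-12)
  }
})
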