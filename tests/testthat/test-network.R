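test_that("edge scores follow the weighted product and inverse laws", {
  regions <- data.frame(region_id = c("A", "B"), x = c(0, 2), y = 0,
                        phenotype = c(2, 3))
  g <- matrix(0L, 1, 2, dimnames = list("L1", c("A", "B")))
  tre <- suppressWarnings(TumorRegionExperiment(g, regions))
  graph <- buildAdjacency(tre, method = "radius", radius = 10)
  pairs <- makeOrderedPairs(graph, tre)

  coop <- scoreEdges(deriveTrait(pairs, "cooperation"))
  comp <- scoreEdges(deriveTrait(pairs, "competition"))
  expect_equal(coop$score, 3)        # 2*3/2
  expect_equal(comp$score, 1 / 12)   # 1/(2*3*2)
  # the two scores of one edge multiply to 1/d^2
  expect_equal(coop$score * comp$score, 1 / coop$distance^2)

  # doubling the distance halves both scores
  regions2 <- regions; regions2$x[2] <- 4
  tre2 <- suppressWarnings(TumorRegionExperiment(g, regions2))
  pairs2 <- makeOrderedPairs(buildAdjacency(tre2, method = "radius",
                                            radius = 10), tre2)
  expect_equal(scoreEdges(deriveTrait(pairs2, "cooperation"))$score,
               coop$score / 2)

  # unweighted tables are rejected
  expect_error(scoreEdges(deriveTrait(pairs, "cooperation",
                                      weightByDistance = FALSE)),
               "weighted")
})

test_that("per-edge score identity holds on a simulated tumor", {
  sim <- simulateTumor(simulationConfig(nRegions = 20, nLoci = 5,
                                        seed = 51))
  tre <- experiment(sim)
  pairs <- makeOrderedPairs(adjacency(sim), tre)
  coop <- scoreEdges(deriveTrait(pairs, "cooperation"))
  comp <- scoreEdges(deriveTrait(pairs, "competition"))
  key <- paste(coop$from, coop$to)
  m <- match(key, paste(comp$from, comp$to))
  expect_equal(coop$score * comp$score[m], 1 / coop$distance^2,
               tolerance = 1e-12)
})

test_that("edge retention by quantile is exact and monotone", {
  scores <- data.frame(from = paste0("a", 1:10), to = paste0("b", 1:10),
                       distance = 1, y_from = 2, y_to = 1,
                       score = seq(0.1, 1, by = 0.1))
  attr(scores, "kind") <- "cooperation"
  net8 <- buildNetwork(scores, edgeQuantile = 0.8)
  expect_equal(nrow(networkEdges(net8)), 2L)
  net0 <- buildNetwork(scores, edgeQuantile = 0)
  expect_equal(nrow(networkEdges(net0)), 10L)
  # monotone: raising the quantile never adds an edge
  counts <- vapply(seq(0, 0.95, by = 0.05), function(q)
    nrow(networkEdges(buildNetwork(scores, edgeQuantile = q))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  # competition edges point from the higher-phenotype inhibitor
  attr(scores, "kind") <- "competition"
  netc <- buildNetwork(scores, edgeQuantile = 0)
  e <- networkEdges(netc)
  expect_true(all(e$from == paste0("a", 1:10)))  # y_from = 2 > y_to = 1
  expect_true(all(e$style == "inhibition"))
})

test_that("hub report ranks by degree with lexicographic ties", {
  edges <- data.frame(from = c("h", "h", "h", "b"),
                      to = c("a", "b", "c", "c"),
                      weight = 1, style = "mutual_activation")
  net <- new("InteractionNetwork", kind = "cooperation",
             nodes = c("a", "b", "c", "h"), edges = edges)
  hubs <- findHubs(net, topK = 2)
  expect_identical(hubs$region_id[1], "h")
  expect_equal(hubs$degree[1], 3L)
  # b and c tie at degree 2: lexicographically smaller first
  expect_identical(hubs$region_id[2:3], c("b", "c"))
  expect_identical(hubs$region_id[hubs$is_hub], c("h", "b"))

  empty <- new("InteractionNetwork", kind = "cooperation",
               nodes = character(0),
               edges = data.frame(from = character(0), to = character(0),
                                  weight = numeric(0),
                                  style = character(0)))
  expect_equal(nrow(findHubs(empty, topK = 1)), 0L)
})

test_that("the strategy matrix is exhausted by the nine sign couples", {
  # cohort engineered so the sign of each region is known exactly
  phen <- setNames(c(1, 1, 1, 5, 5, 5, 9, 9, 9), paste0("r", 1:9))
  # band 0.1: quantiles 0.4/0.6 straddle the middle block of 5s
  lo <- c("r1", "r2"); mid <- c("r4", "r5"); hi <- c("r7", "r8")
  pick <- c("-" = lo[1], "0" = mid[1], "+" = hi[1])
  pick2 <- c("-" = lo[2], "0" = mid[2], "+" = hi[2])
  want <- rbind(
    c("+", "+", "mutualism"),
    c("+", "0", "commensalism"),    c("0", "+", "commensalism"),
    c("+", "-", "predation_parasitism"),
    c("-", "+", "predation_parasitism"),
    c("0", "0", "coexistence"),
    c("0", "-", "amensalism"),      c("-", "0", "amensalism"),
    c("-", "-", "antagonism"))
  labs <- character(9)
  for (i in seq_len(9)) {
    cls <- classifyStrategies(pick[want[i, 1]], pick2[want[i, 2]], phen,
                              neutralBand = 0.1)
    expect_identical(cls$strategy_label, want[i, 3])
    expect_identical(c(cls$sign_from, cls$sign_to), want[i, 1:2])
    # symmetric: swapping the pair keeps the label
    swap <- classifyStrategies(pick2[want[i, 2]], pick[want[i, 1]], phen,
                               neutralBand = 0.1)
    expect_identical(swap$strategy_label, want[i, 3])
    labs[i] <- cls$strategy_label
  }
  expect_setequal(labs, c("mutualism", "commensalism",
                          "predation_parasitism", "coexistence",
                          "amensalism", "antagonism"))

  # degenerate cohort: everything coexists, with a warning
  flat <- setNames(rep(2, 5), paste0("r", 1:5))
  expect_warning(cls <- classifyStrategies("r1", "r2", flat), "degenerate")
  expect_identical(cls$strategy_label, "coexistence")
})

test_that("networks annotate, convert to igraph and write outputs", {
  sim <- simulateTumor(simulationConfig(nRegions = 15, nLoci = 5,
                                        seed = 61))
  tre <- experiment(sim)
  pairs <- makeOrderedPairs(adjacency(sim), tre)
  net <- buildNetwork(scoreEdges(deriveTrait(pairs, "cooperation")),
                      edgeQuantile = 0.5, nodes = regionIds(tre))
  net <- annotateStrategies(net, phenotype(tre))
  expect_true(all(networkEdges(net)$strategy_label %in%
                    c("mutualism", "commensalism", "predation_parasitism",
                      "coexistence", "amensalism", "antagonism")))
  ig <- asIgraph(net)
  expect_equal(igraph::vcount(ig), 15)
  expect_false(igraph::is_directed(ig))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, tsv, gml)
  expect_true(file.exists(tsv))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(networkEdges(net)))
})

test_that("a planted high-cooperation clique fills the retained network", {
  set.seed(71)
  # 16 regions on a grid; a tight 4-clique with high phenotype in a corner
  regions <- data.frame(region_id = sprintf("r%02d", 1:16),
                        x = c(0, 1, 0, 1, rep(c(6, 7, 8, 9), 3)),
                        y = c(0, 0, 1, 1, rep(c(0, 3, 6), each = 4)),
                        phenotype = c(rep(10, 4),
                                      rnorm(12, 1, 0.05)))
  g <- matrix(rbinom(5 * 16, 1, 0.3), 5,
              dimnames = list(paste0("L", 1:5), regions$region_id))
  tre <- suppressWarnings(TumorRegionExperiment(g, regions))
  graph <- buildAdjacency(tre, method = "radius", radius = 100)
  pairs <- makeOrderedPairs(graph, tre)
  scores <- scoreEdges(deriveTrait(pairs, "cooperation"))
  cliqueKey <- apply(combn(sprintf("r%02d", 1:4), 2), 2,
                     function(p) paste(sort(p), collapse = " "))
  q <- 1 - length(cliqueKey) / nrow(scores)
  net <- buildNetwork(scores, edgeQuantile = q)
  got <- paste(pmin(networkEdges(net)$from, networkEdges(net)$to),
               pmax(networkEdges(net)$from, networkEdges(net)$to))
  recall <- mean(cliqueKey %in% got)
  expect_gte(recall, 0.9)
})
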