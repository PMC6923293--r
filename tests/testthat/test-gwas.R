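test_that("segregating-locus filter applies the mutant-count rule", {
  g <- matrix(c(0L, 0L, 0L,
                0L, 1L, 0L,
                1L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("r1", "r2", "r3")))
  expect_identical(rownames(filterSegregating(g, 1L)), c("B", "C"))
  expect_identical(rownames(filterSegregating(g, 2L)), "C")
  mono <- matrix(0L, 2, 3, dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  expect_warning(out <- filterSegregating(mono, 1L), "no segregating")
  expect_equal(nrow(out), 0L)
})

test_that("combination assignment encodes target allele first", {
  tre <- toyExperiment()
  graph <- buildAdjacency(tre, method = "explicit",
                          edgeList = data.frame(region_a = c("r1", "r3"),
                                                region_b = c("r2", "r4")))
  pairs <- makeOrderedPairs(graph, tre)
  # L1 calls: r1=0, r2=1, r3=0, r4=1
  combo <- assignCombinations(pairs, tre, "L1")
  expect_identical(as.character(combo)[pairs$target == "r1"], "GT")
  expect_identical(as.character(combo)[pairs$target == "r2"], "TG")
  # both wild-type on an edge gives GG in both ordered copies
  combo2 <- assignCombinations(pairs, tre, "L2")  # r3=0, r4=0
  expect_identical(as.character(combo2)[pairs$target %in% c("r3", "r4")],
                   c("GG", "GG"))
  # missing call excludes the pair, with a count
  combo3 <- assignCombinations(pairs, tre, "L3")  # r4 = NA
  expect_equal(attr(combo3, "nExcluded"), 2L)
  expect_error(assignCombinations(pairs, tre, "nope"), "unknown locus")
})

test_that("closed-form fits match hand arithmetic and the grid oracle", {
  z <- c(1, 2, 3, 4)
  combo <- factor(c("GG", "GG", "TT", "TT"), levels = c("GG", "GT", "TG",
                                                        "TT"))
  alt <- fitLocus(z, combo, "alternative")
  nul <- fitLocus(z, combo, "null")
  expect_equal(unname(alt@mu[c("GG", "TT")]), c(1.5, 3.5))
  expect_equal(alt@sigma2, 0.25)
  expect_equal(unname(nul@mu), 2.5)
  expect_equal(nul@sigma2, 1.25)
  expect_equal(lrStatistic(alt, nul), 4 * log(5), tolerance = 1e-9)

  # degenerate: all values equal collapses both models (variance floored)
  zc <- rep(2, 4)
  expect_warning(a2 <- fitLocus(zc, combo, "alternative"), "floor")
  expect_warning(n2 <- fitLocus(zc, combo, "null"), "floor")
  expect_equal(lrStatistic(a2, n2), 0)

  # a single non-empty combination makes the models coincide
  z1 <- c(1, 2, 3)
  c1 <- factor(c("GG", "GG", "GG"), levels = levels(combo))
  expect_equal(lrStatistic(fitLocus(z1, c1, "alternative"),
                           fitLocus(z1, c1, "null")), 0)

  # grid-search likelihood maximisation agrees with the closed form
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(4:12, 1)
    zz <- round(rnorm(n, 2, 1), 3)
    cc <- factor(sample(c("GG", "GT", "TG", "TT"), n, replace = TRUE),
                 levels = levels(combo))
    fit <- fitLocus(zz, cc, "alternative")
    expect_equal(fit@logLik, gridFitLogLik(zz, cc), tolerance = 1e-6)
  }

  # mismatched observation counts violate the contract
  expect_error(lrStatistic(fitLocus(z, combo), fitLocus(z1, c1, "null")),
               "different observation counts")
})

test_that("permutation thresholds are deterministic, monotone and degenerate
           to zero for constant phenotypes", {
  sim <- simulateTumor(simulationConfig(nRegions = 18, nLoci = 30,
                                        seed = 21))
  tre <- suppressWarnings(filterSegregating(experiment(sim)))
  graph <- adjacency(sim)
  thr1 <- permutationThreshold(tre, graph, "cooperation", nPerm = 99,
                               alpha = 0.05, seed = 5)
  thr2 <- permutationThreshold(tre, graph, "cooperation", nPerm = 99,
                               alpha = 0.05, seed = 5)
  expect_identical(as.numeric(thr1), as.numeric(thr2))
  expect_identical(attr(thr1, "maxima"), attr(thr2, "maxima"))

  # same permutation set, looser alpha: threshold can only decrease
  thr10 <- permutationThreshold(tre, graph, "cooperation", nPerm = 99,
                                alpha = 0.10, seed = 5)
  expect_lte(as.numeric(thr10), as.numeric(thr1))

  # alpha finer than the permutation resolution warns
  expect_warning(permutationThreshold(tre, graph, "cooperation",
                                      nPerm = 10, alpha = 0.01, seed = 5),
                 "finer than")

  # constant phenotype: every LR is zero, threshold 0, nothing significant
  cd <- colData(experiment(sim))
  regions <- data.frame(region_id = regionIds(experiment(sim)),
                        x = cd$x, y = cd$y, phenotype = 3)
  flat <- TumorRegionExperiment(genotypeCalls(experiment(sim)), regions)
  res <- runGwas(flat, graph, trait = "cooperation", nPerm = 50,
                 alpha = 0.05, seed = 5)
  expect_true(all(res$LR == 0))
  expect_equal(unique(res$threshold), 0)
  expect_false(any(res$significant))
})

test_that("the scan is invariant to positive phenotype rescaling", {
  sim <- simulateTumor(simulationConfig(nRegions = 16, nLoci = 25,
                                        seed = 31))
  tre <- experiment(sim)
  graph <- adjacency(sim)
  res1 <- runGwas(tre, graph, trait = "cooperation", nPerm = 20,
                  alpha = 0.1, seed = 9)
  cd <- colData(tre)
  scaled <- TumorRegionExperiment(genotypeCalls(tre), data.frame(
    region_id = regionIds(tre), x = cd$x, y = cd$y,
    phenotype = 7.3 * phenotype(tre)))
  res2 <- runGwas(scaled, graph, trait = "cooperation", nPerm = 20,
                  alpha = 0.1, seed = 9)
  expect_equal(res1$LR, res2$LR, tolerance = 1e-8)
  # cooperation z itself scales by k^2
  p1 <- deriveTrait(makeOrderedPairs(graph, tre), "cooperation")
  p2 <- deriveTrait(makeOrderedPairs(graph, scaled), "cooperation")
  expect_equal(p2$z, 7.3^2 * p1$z)
})

test_that("a strongly planted locus tops the scan and is significant", {
  cfg <- simulationConfig(nRegions = 23, nLoci = 40, mutantFreq = 0.3,
                          sigma = 0.05,
                          causal = data.frame(locus = 7, a_direct = 2,
                                              a_indirect = 0,
                                              a_epistatic = 0),
                          seed = 77)
  sim <- simulateTumor(cfg)
  res <- runGwas(experiment(sim), adjacency(sim), trait = "cooperation",
                 nPerm = 300, alpha = 0.05, seed = 77)
  expect_identical(res$locus_id[which.max(res$LR)], "L007")
  expect_true(res["L007", "significant"])
})

test_that("per-region phenotype scans use the two-group likelihood", {
  sim <- simulateTumor(simulationConfig(nRegions = 20, nLoci = 20,
                                        seed = 41))
  res <- runGwas(experiment(sim), adjacency(sim), trait = "phenotype",
                 nPerm = 20, alpha = 0.1, seed = 3)
  expect_true(all(res$n_GT == 0))
  expect_true(all(res$n_TG == 0))
  expect_true(all(res$n_GG + res$n_TT <= 20))
  expect_true(all(res$LR >= 0))
})

test_that("a dataset with no segregating loci yields an empty result", {
  regions <- toyRegions()
  g <- matrix(0L, 3, 4, dimnames = list(c("L1", "L2", "L3"),
                                        regions$region_id))
  tre <- TumorRegionExperiment(g, regions)
  expect_warning(res <- runGwas(tre, trait = "phenotype", nPerm = 5,
                                seed = 1),
                 "no segregating")
  expect_equal(nrow(res), 0L)
})
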