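## Synthetic tumors with known direct / indirect / across-cell epistatic
## genetic architecture, for calibration and power studies.

#' Simulation configuration
#'
#' Defaults emulate a microdissected single-tumor design: 23 regions
#' genotyped at 269 biallelic somatic loci, mutant allele frequency 0.2,
#' a strictly positive fitness phenotype (baseline 3, e.g. a ploidy level)
#' with Gaussian noise sd 0.5, regions scattered uniformly on a disk and
#' wired by Delaunay adjacency.
#'
#' @param nRegions number of regions (>= 4).
#' @param nLoci number of biallelic loci.
#' @param mutantFreq mutant allele frequency per locus, in (0, 1); scalar
#'   or per-locus vector.
#' @param causal NULL or data.frame with columns \code{locus} (index or
#'   locus ID), \code{a_direct}, \code{a_indirect}, \code{a_epistatic}
#'   (trait units).
#' @param sigma residual phenotype sd (>= 0, trait units).
#' @param muBase baseline phenotype (> 0).
#' @param layout "uniform_disk" or "grid".
#' @param adjacency list with \code{method} and optional parameters, as for
#'   \code{\link{buildAdjacency}}.
#' @param clusteredClones boost mutant probability inside one random
#'   spatial disk (clonal-patch mode)?
#' @param cloneBoost added mutant probability inside the clone disk.
#' @param seed integer; fully determines the output.
#' @return A validated config list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nRegions = 23L, nLoci = 269L,
                             mutantFreq = 0.2, causal = NULL, sigma = 0.5,
                             muBase = 3, layout = c("uniform_disk", "grid"),
                             adjacency = list(method = "delaunay"),
                             clusteredClones = FALSE, cloneBoost = 0.4,
                             seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(nRegions >= 4L, nLoci >= 1L, sigma >= 0, muBase > 0,
            all(mutantFreq > 0), all(mutantFreq < 1),
            length(mutantFreq) %in% c(1L, nLoci))
  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("locus", "a_direct", "a_indirect", "a_epistatic") %in%
                    colnames(causal)))
  }
  structure(list(nRegions = as.integer(nRegions),
                 nLoci = as.integer(nLoci), mutantFreq = mutantFreq,
                 causal = causal, sigma = sigma, muBase = muBase,
                 layout = layout, adjacency = adjacency,
                 clusteredClones = clusteredClones,
                 cloneBoost = cloneBoost, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a spatially structured tumor
#'
#' Coordinates are drawn per layout, genotypes are i.i.d.
#' Bernoulli(\code{mutantFreq}) per locus and region (optionally boosted
#' inside a random clonal disk), and the phenotype of region \eqn{i} is
#' \deqn{y_i = \mu_{base} + \sum_{causal} \big[a_d g_i +
#'   a_i \bar g_{N(i)} + a_e \overline{g_i g_{N(i)}}\big] + \epsilon_i,
#'   \quad \epsilon_i \sim N(0, \sigma^2),}
#' with neighbour terms averaged over the adjacency neighbourhood
#' \eqn{N(i)} so that effect magnitudes are independent of node degree.
#' Noise is resampled for any region whose phenotype would be nonpositive,
#' keeping ratio and inverse-product traits defined. The same seed
#' reproduces the dataset exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{SyntheticTumor}.
#' @examples
#' sim <- simulateTumor(simulationConfig(nRegions = 23, nLoci = 50,
#'                                       seed = 11))
#' sim
#' @export
simulateTumor <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(childSeed(config$seed, "simulate"))
  n <- config$nRegions
  L <- config$nLoci
  ids <- sprintf("r%02d", seq_len(n))

  xy <- switch(config$layout,
    uniform_disk = {
      r <- sqrt(runif(n)) * 10
      th <- runif(n, 0, 2 * pi)
      cbind(x = r * cos(th), y = r * sin(th))
    },
    grid = {
      side <- ceiling(sqrt(n))
      g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ]
      # tiny deterministic jitter breaks exact cocircularity of grid quads
      as.matrix(g) + matrix(runif(2 * n, -0.01, 0.01), ncol = 2)
    })

  freq <- rep(config$mutantFreq, length.out = L)
  g <- matrix(rbinom(L * n, 1L, rep(freq, times = n)), nrow = L,
              dimnames = list(sprintf("L%03d", seq_len(L)), ids))
  if (config$clusteredClones) {
    ctr <- xy[sample.int(n, 1L), ]
    rad <- quantile(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2),
                    0.3, names = FALSE)
    inside <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) <= rad
    boosted <- pmin(outer(freq, rep(1, n)) +
                      config$cloneBoost * rep(inside, each = L), 0.99)
    g <- matrix(rbinom(L * n, 1L, as.numeric(boosted)), nrow = L,
                dimnames = dimnames(g))
  }

  quad <- paste0(ifelse(xy[, 1] >= median(xy[, 1]), "A", "B"))
  quad <- ifelse(xy[, 2] >= median(xy[, 2]), quad,
                 chartr("AB", "CD", quad))
  regions <- data.frame(region_id = ids, x = xy[, 1], y = xy[, 2],
                        quadrant = quad, phenotype = 1,
                        stringsAsFactors = FALSE)
  tre0 <- suppressWarnings(TumorRegionExperiment(g, regions))
  graph <- do.call(buildAdjacency,
                   c(list(x = tre0), config$adjacency))

  genetic <- rep(0, n)
  truth <- data.frame(locus_id = character(0), a_direct = numeric(0),
                      a_indirect = numeric(0), a_epistatic = numeric(0))
  if (!is.null(config$causal) && nrow(config$causal)) {
    e <- graphEdges(graph)
    nbr <- lapply(setNames(ids, ids), function(i)
      c(e$to[e$from == i], e$from[e$to == i]))
    locId <- function(l) if (is.numeric(l)) rownames(g)[l] else
      as.character(l)
    for (ci in seq_len(nrow(config$causal))) {
      cz <- config$causal[ci, ]
      loc <- locId(cz$locus)
      gi <- g[loc, ]
      nbar <- vapply(ids, function(i) mean(gi[nbr[[i]]]), numeric(1))
      nbar[is.nan(nbar)] <- 0  # isolated region: no neighbour input
      genetic <- genetic + cz$a_direct * gi + cz$a_indirect * nbar +
        cz$a_epistatic * gi * nbar
      truth <- rbind(truth,
                     data.frame(locus_id = loc, a_direct = cz$a_direct,
                                a_indirect = cz$a_indirect,
                                a_epistatic = cz$a_epistatic))
    }
  }
  y <- config$muBase + genetic + rnorm(n, 0, config$sigma)
  tries <- 0L
  while (any(y <= 0)) {
    bad <- y <= 0
    y[bad] <- config$muBase + genetic[bad] +
      rnorm(sum(bad), 0, config$sigma)
    tries <- tries + 1L
    if (tries > 1000L)
      stop("could not draw positive phenotypes; muBase too small ",
           "relative to sigma and negative genetic effects")
  }
  regions$phenotype <- y
  tre <- TumorRegionExperiment(g, regions)
  new("SyntheticTumor", experiment = tre, graph = graph, truth = truth,
      config = unclass(config))
}

#' @rdname SyntheticTumor-accessors
#' @export
setGeneric("experiment", function(x, ...) standardGeneric("experiment"))

#' @rdname SyntheticTumor-accessors
#' @export
setGeneric("adjacency", function(x, ...) standardGeneric("adjacency"))

#' @rdname SyntheticTumor-accessors
#' @export
setGeneric("truthTable", function(x, ...) standardGeneric("truthTable"))

#' Accessors for SyntheticTumor
#'
#' @param x a \linkS4class{SyntheticTumor}.
#' @param ... unused.
#' @return \code{experiment}: the simulated
#'   \linkS4class{TumorRegionExperiment}; \code{adjacency}: its
#'   \linkS4class{RegionGraph}; \code{truthTable}: the planted causal
#'   effects.
#' @name SyntheticTumor-accessors
NULL

#' @rdname SyntheticTumor-accessors
#' @export
setMethod("experiment", "SyntheticTumor", function(x, ...) x@experiment)

#' @rdname SyntheticTumor-accessors
#' @export
setMethod("adjacency", "SyntheticTumor", function(x, ...) x@graph)

#' @rdname SyntheticTumor-accessors
#' @export
setMethod("truthTable", "SyntheticTumor", function(x, ...) x@truth)

#' Write a synthetic tumor to a directory
#'
#' Emits the region table, genotype matrix, adjacency edge list and truth
#' table in the package's TSV formats plus a YAML echo of the
#' configuration; everything round-trips through the package readers.
#'
#' @param sim a \linkS4class{SyntheticTumor}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticTumor <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tre <- experiment(sim)
  regions <- data.frame(region_id = regionIds(tre),
                        x = colData(tre)$x, y = colData(tre)$y,
                        quadrant = colData(tre)$quadrant,
                        phenotype = colData(tre)$phenotype)
  writeRegionTable(regions, file.path(dir, "regions.tsv"))
  writeGenotypeMatrix(genotypeCalls(tre), file.path(dir, "genotypes.tsv"))
  writeAdjacencyList(adjacency(sim), file.path(dir, "adjacency.tsv"))
  con <- file(file.path(dir, "truth.tsv"), "w")
  writeLines(.toolHeader(), con)
  write.table(truthTable(sim), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  cfg <- sim@config
  cfg$causal <- if (is.null(cfg$causal)) NULL else as.list(cfg$causal)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Recovery metrics against the planted truth
#'
#' Detection power = fraction of planted causal loci flagged significant in
#' the scan; false-positive rate = fraction of non-causal loci flagged.
#' Effect bias/RMSE compare \code{\link{estimateSocialEffects}} estimates
#' (phenotype scale, the generator's own design) with the planted values.
#'
#' @param gwas a \linkS4class{GwasResults} run on the synthetic dataset.
#' @param effects output of \code{\link{estimateSocialEffects}} on the same
#'   dataset (may be NULL to skip bias metrics).
#' @param truth the \code{\link{truthTable}} of the simulation.
#' @return list with \code{power}, \code{fpr}, \code{nCausal},
#'   \code{effectErrors} (per causal locus: estimate, truth, error for each
#'   effect).
#' @export
truthRecoveryReport <- function(gwas, effects = NULL, truth) {
  if (!all(truth$locus_id %in% gwas$locus_id))
    stop("truth table names loci absent from the scan results")
  causal <- gwas$locus_id %in% truth$locus_id
  power <- if (any(causal)) mean(gwas$significant[causal]) else NA_real_
  fpr <- if (any(!causal)) mean(gwas$significant[!causal]) else NA_real_
  effectErrors <- NULL
  if (!is.null(effects) && nrow(truth)) {
    if (!all(truth$locus_id %in% effects$locus_id))
      stop("truth table names loci absent from the effect estimates")
    m <- match(truth$locus_id, effects$locus_id)
    effectErrors <- data.frame(
      locus_id = truth$locus_id,
      est_direct = effects$a_direct[m], true_direct = truth$a_direct,
      est_indirect = effects$a_indirect[m],
      true_indirect = truth$a_indirect,
      est_epistatic = effects$a_epistatic[m],
      true_epistatic = truth$a_epistatic)
    effectErrors$err_direct <-
      effectErrors$est_direct - effectErrors$true_direct
    effectErrors$err_indirect <-
      effectErrors$est_indirect - effectErrors$true_indirect
    effectErrors$err_epistatic <-
      effectErrors$est_epistatic - effectErrors$true_epistatic
  }
  list(power = power, fpr = fpr, nCausal = nrow(truth),
       effectErrors = effectErrors)
}
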