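## End-to-end orchestration: read -> validate -> pair -> scan -> decompose
## -> network, with a config echo and a run log in the output directory.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reads a region table and genotype matrix, validates them, builds the
#' spatial adjacency, and for every requested trait runs the
#' segregating-locus filter, the paired likelihood-ratio scan with its
#' genome-wide permutation threshold, the effect decomposition of
#' significant loci, and (for cooperation/competition) the interaction
#' network with hub report and strategy labels. All tables are written as
#' versioned TSVs plus GraphML networks; the resolved configuration is
#' echoed to \code{config.yaml} and counts of every filtering step go to
#' \code{run.log}.
#'
#' @param regionFile region-table TSV path.
#' @param genotypeFile genotype path (TSV or VCF; see
#'   \code{\link{readGenotypeMatrix}}).
#' @param outDir output directory.
#' @param genotypeFormat "tsv" or "vcf".
#' @param adjacencyMethod,k,radius,adjacencyFile adjacency construction;
#'   \code{adjacencyFile} switches to an explicit edge list.
#' @param traits trait kinds to scan.
#' @param nPerm,alpha,minMinorCount,seed,weightByDistance,orderedPairs,logTransform
#'   scan settings; see \code{\link{runGwas}}.
#' @param edgeQuantile,neutralBand,topKHubs network settings.
#' @return Invisible list of per-trait results and networks.
#' @export
runPipeline <- function(regionFile, genotypeFile, outDir,
                        genotypeFormat = c("tsv", "vcf"),
                        adjacencyMethod = "delaunay", k = 2L,
                        radius = NULL, adjacencyFile = NULL,
                        traits = c("cooperation", "altruism",
                                   "competition"),
                        nPerm = 1000L, alpha = 0.01, minMinorCount = 2L,
                        seed = 1L, weightByDistance = FALSE,
                        orderedPairs = "both", logTransform = FALSE,
                        edgeQuantile = 0.8, neutralBand = 0.1,
                        topKHubs = 4L) {
  genotypeFormat <- match.arg(genotypeFormat)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLines <- c(.toolHeader(), sprintf("seed: %d", seed))
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  regions <- .stage("io", readRegionTable(regionFile))
  genotypes <- .stage("io", readGenotypeMatrix(genotypeFile,
                                               genotypeFormat))
  note("regions read: %d; loci read: %d", nrow(regions), nrow(genotypes))
  tre <- .stage("validate", TumorRegionExperiment(genotypes, regions))
  note("validated dataset: %d loci x %d regions", nrow(tre), ncol(tre))

  graph <- .stage("adjacency", {
    if (!is.null(adjacencyFile))
      buildAdjacency(tre, method = "explicit",
                     edgeList = readAdjacencyList(adjacencyFile))
    else
      buildAdjacency(tre, method = adjacencyMethod, k = k,
                     radius = radius)
  })
  note("adjacency (%s): %d edges", graph@method, nrow(graphEdges(graph)))
  writeAdjacencyList(graph, file.path(outDir, "adjacency.tsv"))

  nSeg <- nrow(suppressWarnings(filterSegregating(tre, minMinorCount)))
  note("segregating loci (minor count >= %d): %d of %d", minMinorCount,
       nSeg, nrow(tre))

  out <- list()
  for (trait in traits) {
    res <- .stage(paste0("gwas-", trait),
                  runGwas(tre, graph, trait = trait, nPerm = nPerm,
                          alpha = alpha, minMinorCount = minMinorCount,
                          seed = seed, weightByDistance = weightByDistance,
                          orderedPairs = orderedPairs,
                          logTransform = logTransform))
    writeGwasResults(res, file.path(outDir,
                                    sprintf("gwas_%s.tsv", trait)))
    mt <- manhattanTable(res)
    con <- file(file.path(outDir, sprintf("manhattan_%s.tsv", trait)), "w")
    writeLines(.toolHeader(), con)
    write.table(mt, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    note("%s: %d/%d loci significant (threshold %.4f)", trait,
         sum(res$significant), nrow(res),
         if (nrow(res)) res$threshold[1] else NA)
    dec <- NULL
    if (trait != "phenotype" && nrow(res) && any(res$significant)) {
      xs <- suppressWarnings(filterSegregating(tre, minMinorCount))
      dec <- .stage(paste0("decompose-", trait),
                    decomposeLoci(xs, graph, results = res, trait = trait,
                                  weightByDistance = weightByDistance,
                                  orderedPairs = orderedPairs))
      writeDecomposition(dec, file.path(outDir,
                                        sprintf("decomposition_%s.tsv",
                                                trait)))
      note("%s: %d locus/loci decomposed", trait, nrow(dec))
    }
    net <- NULL
    if (trait %in% c("cooperation", "competition")) {
      net <- .stage(paste0("network-", trait), {
        pairs <- deriveTrait(makeOrderedPairs(graph, tre), kind = trait,
                             weightByDistance = TRUE)
        nw <- buildNetwork(scoreEdges(pairs),
                           edgeQuantile = edgeQuantile,
                           nodes = regionIds(tre))
        annotateStrategies(nw, phenotype(tre), neutralBand)
      })
      writeNetwork(net, file.path(outDir,
                                  sprintf("network_%s.tsv", trait)),
                   file.path(outDir,
                             sprintf("network_%s.graphml", trait)))
      hubs <- findHubs(net, topK = topKHubs)
      con <- file(file.path(outDir, sprintf("hubs_%s.tsv", trait)), "w")
      writeLines(.toolHeader(), con)
      write.table(as.data.frame(hubs), con, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      close(con)
      note("%s network: %d edges, top hub %s", trait,
           nrow(networkEdges(net)),
           if (nrow(hubs)) hubs$region_id[1] else "none")
    }
    out[[trait]] <- list(gwas = res, decomposition = dec, network = net)
  }

  cfg <- list(regionFile = regionFile, genotypeFile = genotypeFile,
              genotypeFormat = genotypeFormat,
              adjacencyMethod = adjacencyMethod, k = k, radius = radius,
              adjacencyFile = adjacencyFile, traits = traits,
              nPerm = nPerm, alpha = alpha, minMinorCount = minMinorCount,
              seed = seed, weightByDistance = weightByDistance,
              orderedPairs = orderedPairs, logTransform = logTransform,
              edgeQuantile = edgeQuantile, neutralBand = neutralBand,
              topKHubs = topKHubs, version = .pkgVersion())
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  writeLines(logLines, logPath)
  invisible(out)
}
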