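#' Family-wise error calibration of the permutation threshold
#'
#' Runs the null-calibration experiment behind the package's headline
#' guarantee: replicate synthetic tumors are drawn with genotypes
#' independent of the phenotype (no causal loci), each scanned with the
#' cooperation-trait likelihood-ratio GWAS and its genome-wide permutation
#' threshold, and the fraction of replicates in which any locus is declared
#' significant estimates the family-wise type-I error, which should match
#' \code{alpha}. Each replicate uses \code{nRegions} regions on a Delaunay
#' adjacency and exactly \code{nSegregating} segregating loci (loci are
#' drawn at \code{mutantFreq} until enough segregate, then the first
#' \code{nSegregating} are scanned). Per-replicate seeds derive from the
#' master seed via \code{\link{childSeed}}.
#'
#' @param seed master seed.
#' @param nReplicates number of null tumors.
#' @param nPerm permutations per replicate.
#' @param alpha genome-wide level.
#' @param nRegions regions per tumor.
#' @param nSegregating segregating loci entering each scan.
#' @param mutantFreq mutant allele frequency.
#' @return list with \code{fwer} (rejection fraction), \code{rejections}
#'   (logical per replicate) and the settings.
#' @export
fwerCalibration <- function(seed = 1L, nReplicates = 200L, nPerm = 1000L,
                            alpha = 0.01, nRegions = 23L,
                            nSegregating = 50L, mutantFreq = 0.2) {
  rejections <- vapply(seq_len(nReplicates), function(i) {
    dsSeed <- childSeed(seed, sprintf("fwer-dataset-%03d", i))
    xs <- NULL
    for (try in 0:9) {
      cfg <- simulationConfig(
        nRegions = nRegions, nLoci = max(2L * nSegregating, 30L),
        mutantFreq = mutantFreq,
        seed = (dsSeed + try * 1000003) %% 2147483647)
      sim <- simulateTumor(cfg)
      cand <- suppressWarnings(filterSegregating(experiment(sim), 2L))
      if (nrow(cand) >= nSegregating) {
        xs <- cand[seq_len(nSegregating), ]
        break
      }
    }
    if (is.null(xs))
      stop("could not draw ", nSegregating, " segregating loci")
    res <- runGwas(xs, adjacency(sim), trait = "cooperation",
                   nPerm = nPerm, alpha = alpha, minMinorCount = 2L,
                   seed = dsSeed)
    any(res$significant)
  }, logical(1))
  list(fwer = mean(rejections), rejections = rejections,
       nReplicates = nReplicates, nPerm = nPerm, alpha = alpha,
       nRegions = nRegions, nSegregating = nSegregating, seed = seed)
}
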