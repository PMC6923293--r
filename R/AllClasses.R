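#' @title Core S4 classes
#' @name tumorRewire-classes
#' @keywords internal
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' TumorRegionExperiment: genotyped, phenotyped tumor regions
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are somatic mutation loci,
#' columns are spatially resolved tumor regions (cell populations). The
#' \code{"genotype"} assay holds binary calls (0 = wild-type "G", 1 = mutant
#' "T", \code{NA} = missing); \code{colData} carries the planar coordinates
#' \code{x}, \code{y}, an optional \code{quadrant} label and the
#' fitness-related \code{phenotype} (e.g. ploidy level); \code{rowData}
#' carries \code{locus_id} and optional \code{chrom}.
#'
#' @export
setClass("TumorRegionExperiment", contains = "SummarizedExperiment")

setValidity("TumorRegionExperiment", function(object) {
  msg <- character()
  if (!"genotype" %in% assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- assay(object, "genotype")
    bad <- !(g %in% c(0L, 1L) | is.na(g))
    if (any(bad))
      msg <- c(msg, "genotype calls must be 0, 1 or NA")
  }
  cd <- colData(object)
  need <- c("x", "y", "phenotype")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, sprintf("colData lacks column(s): %s",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate region IDs")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate locus IDs")
  if ("phenotype" %in% colnames(cd) && any(!is.finite(cd$phenotype)))
    msg <- c(msg, "phenotype must be finite for every retained region")
  if (length(msg)) msg else TRUE
})

#' Construct (and validate) a TumorRegionExperiment
#'
#' Aligns a genotype matrix with a region table, mirroring the dataset
#' validation contract: duplicate region IDs are an error, regions with a
#' missing phenotype are dropped with a warning, genotype columns without a
#' matching region record (and vice versa) are dropped with a warning, and
#' zero overlap between the two inputs is an error. The operation is
#' idempotent: rebuilding from a validated object's components returns an
#' identical object.
#'
#' @param genotypes integer matrix (loci x regions) with values in
#'   \{0, 1, NA\}; rownames = locus IDs, colnames = region IDs. An optional
#'   \code{"chrom"} attribute (per-locus chromosome labels) is kept.
#' @param regions data.frame with columns \code{region_id}, \code{x},
#'   \code{y}, optional \code{quadrant}, \code{phenotype} (as returned by
#'   \code{\link{readRegionTable}}).
#' @return A validated \linkS4class{TumorRegionExperiment}.
#' @examples
#' regions <- data.frame(region_id = c("r1", "r2", "r3"),
#'                       x = c(0, 1, 0), y = c(0, 0, 1),
#'                       phenotype = c(2, 3, 4))
#' g <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("L1", "L2"), c("r1", "r2", "r3")))
#' tre <- TumorRegionExperiment(g, regions)
#' @export
TumorRegionExperiment <- function(genotypes, regions) {
  stopifnot(is.matrix(genotypes), is.data.frame(regions))
  need <- c("region_id", "x", "y", "phenotype")
  miss <- setdiff(need, colnames(regions))
  if (length(miss))
    stop("region table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(regions$region_id))
    stop("duplicate region IDs: ",
         paste(unique(regions$region_id[duplicated(regions$region_id)]),
               collapse = ", "))
  if (is.null(colnames(genotypes)) || is.null(rownames(genotypes)))
    stop("genotype matrix must carry locus rownames and region colnames")
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate locus IDs in genotype matrix")

  nope <- !is.finite(regions$phenotype)
  if (any(nope)) {
    warning(sum(nope), " region(s) dropped for missing phenotype: ",
            paste(regions$region_id[nope], collapse = ", "))
    regions <- regions[!nope, , drop = FALSE]
  }
  ids <- intersect(regions$region_id, colnames(genotypes))
  if (length(ids) == 0L)
    stop("no overlapping region IDs between region table and genotype matrix")
  extraG <- setdiff(colnames(genotypes), ids)
  if (length(extraG))
    warning(length(extraG), " genotype column(s) without region record ",
            "dropped: ", paste(extraG, collapse = ", "))
  extraR <- setdiff(regions$region_id, ids)
  if (length(extraR))
    warning(length(extraR), " region(s) without genotype column dropped: ",
            paste(extraR, collapse = ", "))
  regions <- regions[regions$region_id %in% ids, , drop = FALSE]
  ids <- regions$region_id  # keep region-table order

  calls <- genotypes[, ids, drop = FALSE]
  storage.mode(calls) <- "integer"
  chrom <- attr(genotypes, "chrom")
  rd <- DataFrame(locus_id = rownames(calls),
                  chrom = if (is.null(chrom)) NA_character_ else
                    as.character(chrom),
                  row.names = rownames(calls))
  cd <- DataFrame(x = as.numeric(regions$x), y = as.numeric(regions$y),
                  quadrant = if ("quadrant" %in% colnames(regions))
                    as.character(regions$quadrant) else NA_character_,
                  phenotype = as.numeric(regions$phenotype),
                  row.names = ids)
  se <- SummarizedExperiment(assays = list(genotype = calls),
                             rowData = rd, colData = cd)
  new("TumorRegionExperiment", se)
}

#' RegionGraph: spatial adjacency among tumor regions
#'
#' A simple undirected graph over region IDs with a Euclidean distance per
#' edge. Built by \code{\link{buildAdjacency}}.
#'
#' @slot nodes character vector of region IDs.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{distance}; one row per undirected edge, \code{from} preceding
#'   \code{to} in node order.
#' @slot method character; how the graph was built.
#' @export
setClass("RegionGraph",
         representation(nodes = "character", edges = "data.frame",
                        method = "character"))

setValidity("RegionGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "distance") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, distance")
  else {
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be graph nodes")
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (nrow(e) && any(!is.finite(e$distance) | e$distance <= 0))
      msg <- c(msg, "edge distances must be finite and > 0")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' GwasResults: per-locus association scan results
#'
#' A \linkS4class{DFrame} with one row per tested locus (combination counts
#' and means, pooled variance, LR statistic, significance against the
#' genome-wide permutation threshold, variance explained) and scan settings
#' in \code{metadata()} (\code{trait}, \code{nPerm}, \code{alpha},
#' \code{threshold}, \code{seed}, \code{maxima} — the permutation null of
#' genome-wide maximum LR values).
#'
#' @export
setClass("GwasResults", contains = "DFrame")

#' LocusFit: a Gaussian fit of combination means
#'
#' @slot mu named numeric; one mean per non-empty genotype combination
#'   (alternative model) or the single grand mean (null model).
#' @slot sigma2 numeric(1); pooled maximum-likelihood variance (divisor n),
#'   clamped to the variance floor.
#' @slot logLik numeric(1); Gaussian log-likelihood at the estimates.
#' @slot k integer(1); number of free mean parameters.
#' @slot n integer(1); number of observations used.
#' @slot model character(1); "alternative" or "null".
#' @export
setClass("LocusFit",
         representation(mu = "numeric", sigma2 = "numeric",
                        logLik = "numeric", k = "integer", n = "integer",
                        model = "character"))

#' InteractionNetwork: a rewired cooperation or competition network
#'
#' @slot kind "cooperation" or "competition".
#' @slot nodes character vector of region IDs (isolated nodes retained).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (distance-weighted derivative score), \code{style}
#'   ("mutual_activation" for cooperation, "inhibition" for competition; for
#'   inhibition \code{from} is the higher-phenotype inhibitor) and, once
#'   \code{\link{classifyStrategies}} has run, \code{strategy_label}.
#' @export
setClass("InteractionNetwork",
         representation(kind = "character", nodes = "character",
                        edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  if (!object@kind %in% c("cooperation", "competition"))
    msg <- c(msg, "kind must be 'cooperation' or 'competition'")
  e <- object@edges
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e$weight < 0)) msg <- c(msg, "edge weights must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTumor: a simulated dataset with known genetic architecture
#'
#' @slot experiment the simulated \linkS4class{TumorRegionExperiment}.
#' @slot graph the \linkS4class{RegionGraph} the indirect/epistatic effects
#'   were propagated on.
#' @slot truth data.frame of planted causal effects (\code{locus_id},
#'   \code{a_direct}, \code{a_indirect}, \code{a_epistatic}); zero rows for a
#'   null tumor.
#' @slot config the \code{\link{simulationConfig}} used.
#' @export
setClass("SyntheticTumor",
         representation(experiment = "TumorRegionExperiment",
                        graph = "RegionGraph", truth = "data.frame",
                        config = "list"))
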