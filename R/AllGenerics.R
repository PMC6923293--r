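#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x, ...) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setGeneric("regionCoords", function(x, ...) standardGeneric("regionCoords"))

#' @rdname accessors
#' @export
setGeneric("quadrants", function(x, ...) standardGeneric("quadrants"))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x, ...) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("lociIds", function(x, ...) standardGeneric("lociIds"))

#' @rdname RegionGraph-accessors
#' @export
setGeneric("graphEdges", function(x, ...) standardGeneric("graphEdges"))

#' @rdname RegionGraph-accessors
#' @export
setGeneric("graphNodes", function(x, ...) standardGeneric("graphNodes"))

#' @rdname filterSegregating
#' @export
setGeneric("filterSegregating",
           function(x, minMinorCount = 2L, ...)
             standardGeneric("filterSegregating"))

#' @rdname networkEdges
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' Accessors for TumorRegionExperiment
#'
#' \code{genotypeCalls} returns the loci x regions call matrix (0 =
#' wild-type, 1 = mutant, NA = missing); \code{phenotype} the named
#' fitness-phenotype vector; \code{regionCoords} the two-column coordinate
#' matrix; \code{quadrants} the optional quadrant labels; \code{regionIds}
#' and \code{lociIds} the identifiers.
#'
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param ... unused.
#' @return See the per-accessor description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "TumorRegionExperiment",
          function(x, ...) assay(x, "genotype"))

#' @rdname accessors
#' @export
setMethod("phenotype", "TumorRegionExperiment", function(x, ...)
  setNames(colData(x)$phenotype, colnames(x)))

#' @rdname accessors
#' @export
setMethod("regionCoords", "TumorRegionExperiment", function(x, ...) {
  m <- cbind(x = colData(x)$x, y = colData(x)$y)
  rownames(m) <- colnames(x)
  m
})

#' @rdname accessors
#' @export
setMethod("quadrants", "TumorRegionExperiment", function(x, ...)
  setNames(colData(x)$quadrant, colnames(x)))

#' @rdname accessors
#' @export
setMethod("regionIds", "TumorRegionExperiment", function(x, ...) colnames(x))

#' @rdname accessors
#' @export
setMethod("lociIds", "TumorRegionExperiment", function(x, ...) rownames(x))

#' Accessors for RegionGraph
#'
#' @param x a \linkS4class{RegionGraph}.
#' @param ... unused.
#' @return \code{graphEdges}: the edge data.frame (\code{from}, \code{to},
#'   \code{distance}); \code{graphNodes}: the node IDs.
#' @name RegionGraph-accessors
NULL

#' @rdname RegionGraph-accessors
#' @export
setMethod("graphEdges", "RegionGraph", function(x, ...) x@edges)

#' @rdname RegionGraph-accessors
#' @export
setMethod("graphNodes", "RegionGraph", function(x, ...) x@nodes)

setMethod("show", "TumorRegionExperiment", function(object) {
  callNextMethod()
  cat(sprintf("phenotype range: [%.4g, %.4g]\n",
              min(colData(object)$phenotype),
              max(colData(object)$phenotype)))
})

setMethod("show", "RegionGraph", function(object) {
  cat(sprintf("RegionGraph (%s): %d regions, %d edges\n", object@method,
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "LocusFit", function(object) {
  cat(sprintf("LocusFit (%s): n=%d, k=%d, sigma2=%.6g, lnL=%.6g\n",
              object@model, object@n, object@k, object@sigma2,
              object@logLik))
  print(object@mu)
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork (%s): %d regions, %d edges\n",
              object@kind, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "SyntheticTumor", function(object) {
  cat(sprintf("SyntheticTumor: %d regions x %d loci, %d causal locus/loci\n",
              ncol(object@experiment), nrow(object@experiment),
              nrow(object@truth)))
})

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x, ...) x@edges)

#' Edge table of an interaction network
#'
#' @param x an \linkS4class{InteractionNetwork}.
#' @param ... unused.
#' @return data.frame of edges with weights, styles and (if classified)
#'   strategy labels.
#' @name networkEdges
NULL
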