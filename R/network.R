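## Rewiring cooperative/competitive interaction networks among regions,
## hub detection, and game-theoretic strategy classification.

#' Distance-weighted interaction scores per undirected edge
#'
#' From a derivative-trait pair table (computed with distance weighting),
#' collapses the two ordered copies of each edge to one undirected score:
#' cooperation \eqn{y_i y_j / d_{ij}}, competition
#' \eqn{1 / (y_i y_j d_{ij})}. The two scores of the same edge multiply to
#' \eqn{1 / d^2}.
#'
#' @param pairs output of \code{\link{deriveTrait}} with
#'   \code{kind} "cooperation" or "competition" and distance weighting on.
#' @return data.frame \code{from}, \code{to}, \code{distance},
#'   \code{y_from}, \code{y_to}, \code{score} with attribute \code{"kind"}.
#' @export
scoreEdges <- function(pairs) {
  kind <- metadata(pairs)$kind
  if (!kind %in% c("cooperation", "competition"))
    stop("scoreEdges needs a cooperation or competition trait table")
  if (!isTRUE(metadata(pairs)$weighted))
    stop("scoreEdges needs distance-weighted trait values")
  key <- paste(pmin(pairs$target, pairs$partner),
               pmax(pairs$target, pairs$partner))
  keep <- !duplicated(key)
  out <- data.frame(from = pairs$target[keep], to = pairs$partner[keep],
                    distance = pairs$distance[keep],
                    y_from = pairs$y_target[keep],
                    y_to = pairs$y_partner[keep],
                    score = pairs$z_weighted[keep],
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  out
}

#' Build an interaction network from edge scores
#'
#' Retains edges whose score is at or above the \code{edgeQuantile}
#' empirical quantile of all scores of that kind (\code{edgeQuantile = 0}
#' keeps everything). Cooperation edges are mutual activations; competition
#' edges are rendered as inhibition of the lower-phenotype member by the
#' higher-phenotype member (the direction of the altruism ratio).
#'
#' @param scores output of \code{\link{scoreEdges}}.
#' @param edgeQuantile fraction in \[0, 1).
#' @param nodes optional full node set (isolated regions retained).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
buildNetwork <- function(scores, edgeQuantile = 0.8, nodes = NULL) {
  stopifnot(edgeQuantile >= 0, edgeQuantile < 1)
  kind <- attr(scores, "kind")
  if (is.null(nodes)) nodes <- sort(unique(c(scores$from, scores$to)))
  if (nrow(scores) == 0L)
    return(new("InteractionNetwork", kind = kind, nodes = nodes,
               edges = data.frame(from = character(0), to = character(0),
                                  weight = numeric(0),
                                  style = character(0))))
  cut <- if (edgeQuantile == 0) -Inf else
    quantile(scores$score, edgeQuantile, names = FALSE)
  kept <- scores[scores$score >= cut, , drop = FALSE]
  if (kind == "cooperation") {
    edges <- data.frame(from = kept$from, to = kept$to,
                        weight = kept$score,
                        style = rep("mutual_activation", nrow(kept)),
                        stringsAsFactors = FALSE)
  } else {
    swap <- kept$y_to > kept$y_from   # inhibitor = larger phenotype
    edges <- data.frame(from = ifelse(swap, kept$to, kept$from),
                        to = ifelse(swap, kept$from, kept$to),
                        weight = kept$score,
                        style = rep("inhibition", nrow(kept)),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  new("InteractionNetwork", kind = kind, nodes = nodes, edges = edges)
}

#' Hub regions of an interaction network
#'
#' Hubs are the regions connected with the most other regions: nodes ranked
#' by degree (number of incident edges, direction ignored), ties broken
#' lexicographically by region ID.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param topK number of hubs to flag (>= 1).
#' @return \linkS4class{DFrame} of all nodes with \code{region_id},
#'   \code{degree}, \code{rank}, \code{is_hub}; \code{metadata()$topK}
#'   records the cut. Zero rows for an empty network.
#' @export
findHubs <- function(network, topK = 4L) {
  stopifnot(topK >= 1L)
  nodes <- network@nodes
  if (length(nodes) == 0L) {
    out <- DataFrame(region_id = character(0), degree = integer(0),
                     rank = integer(0), is_hub = logical(0))
    metadata(out)$topK <- topK
    return(out)
  }
  e <- network@edges
  deg <- table(factor(c(e$from, e$to), levels = nodes))
  o <- order(-as.integer(deg), names(deg))
  out <- DataFrame(region_id = names(deg)[o],
                   degree = as.integer(deg)[o],
                   rank = seq_along(nodes),
                   is_hub = seq_along(nodes) <= topK)
  metadata(out)$topK <- topK
  out
}

.STRATEGY <- c("+/+" = "mutualism",
               "+/0" = "commensalism", "0/+" = "commensalism",
               "+/-" = "predation_parasitism",
               "-/+" = "predation_parasitism",
               "0/0" = "coexistence",
               "0/-" = "amensalism", "-/0" = "amensalism",
               "-/-" = "antagonism")

#' Classify adjacent pairs by the ecological strategy matrix
#'
#' Each region's strategy sign is read off the cohort phenotype
#' distribution: \code{+} above the \code{0.5 + neutralBand} quantile,
#' \code{-} below the \code{0.5 - neutralBand} quantile, \code{0} in the
#' neutral band between. The ordered sign couple of a pair addresses the
#' 3x3 strategy matrix — mutualism (+/+), commensalism (+/0, 0/+),
#' predation/parasitism (+/-, -/+), peaceful coexistence (0/0), amensalism
#' (0/-, -/0), antagonism (-/-). Labels are symmetric in the pair order.
#' A degenerate cohort (all phenotypes equal) classifies every pair as
#' coexistence, with a warning.
#'
#' @param from,to character vectors of region IDs forming the pairs.
#' @param phenotype named phenotype vector of the whole cohort.
#' @param neutralBand half-width of the neutral quantile band, in
#'   \[0, 0.5).
#' @return data.frame \code{from}, \code{to}, \code{sign_from},
#'   \code{sign_to}, \code{strategy_label}.
#' @export
classifyStrategies <- function(from, to, phenotype, neutralBand = 0.1) {
  stopifnot(neutralBand >= 0, neutralBand < 0.5)
  if (diff(range(phenotype)) == 0) {
    warning("degenerate cohort (all phenotypes equal); every pair ",
            "classified as coexistence")
    sgn <- setNames(rep("0", length(phenotype)), names(phenotype))
  } else {
    qHi <- quantile(phenotype, 0.5 + neutralBand, names = FALSE)
    qLo <- quantile(phenotype, 0.5 - neutralBand, names = FALSE)
    sgn <- setNames(ifelse(phenotype > qHi, "+",
                           ifelse(phenotype < qLo, "-", "0")),
                    names(phenotype))
  }
  key <- paste0(sgn[from], "/", sgn[to])
  data.frame(from = from, to = to, sign_from = unname(sgn[from]),
             sign_to = unname(sgn[to]),
             strategy_label = unname(.STRATEGY[key]),
             stringsAsFactors = FALSE)
}

#' Annotate a network's edges with strategy labels
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param phenotype named cohort phenotype vector.
#' @param neutralBand see \code{\link{classifyStrategies}}.
#' @return The network with a \code{strategy_label} edge column.
#' @export
annotateStrategies <- function(network, phenotype, neutralBand = 0.1) {
  e <- network@edges
  if (nrow(e)) {
    cls <- classifyStrategies(e$from, e$to, phenotype, neutralBand)
    e$strategy_label <- cls$strategy_label
  } else e$strategy_label <- character(0)
  initialize(network, edges = e)
}

#' Convert an interaction network to igraph
#'
#' Cooperation networks are undirected (mutual activation); competition
#' networks directed (inhibitor to inhibited).
#'
#' @param x an \linkS4class{InteractionNetwork}.
#' @param ... unused.
#' @return An \code{igraph} graph with edge attributes \code{weight},
#'   \code{style} (and \code{strategy_label} if annotated).
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x, ...) {
  igraph::graph_from_data_frame(x@edges,
                                directed = x@kind == "competition",
                                vertices = data.frame(name = x@nodes))
})

#' Write an interaction network (TSV edge list and GraphML)
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param tsvPath edge-list TSV path
#'   (\code{source target kind weight style strategy_label}).
#' @param graphmlPath optional GraphML path.
#' @return \code{tsvPath}, invisibly.
#' @export
writeNetwork <- function(network, tsvPath, graphmlPath = NULL) {
  e <- network@edges
  df <- data.frame(source = e$from, target = e$to,
                   kind = rep(network@kind, nrow(e)),
                   weight = e$weight, style = e$style,
                   strategy_label = if ("strategy_label" %in% colnames(e))
                     e$strategy_label else NA_character_)
  con <- file(tsvPath, "w")
  writeLines(.toolHeader(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(graphmlPath))
    igraph::write_graph(asIgraph(network), graphmlPath, format = "graphml")
  invisible(tsvPath)
}
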