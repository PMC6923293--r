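## Spatial pairing: adjacency graphs among regions and ordered pairs with
## derivative interaction traits.

## Delaunay edge set via the empty-circumcircle characterisation: (i, j) is a
## Delaunay edge iff some circle through i and j contains no other point.
## Circle centres live on the perpendicular bisector c(t) = m + t*u; point k
## lies strictly outside the circle through i, j centred at c(t) iff
## A_k + t * B_k > 0 with A_k = |m-k|^2 - |m-i|^2 and B_k = 2 u.(i-k).
## Feasibility of the resulting half-line intersection is an O(n) test per
## pair, O(n^3) overall — ample for the tens-to-hundreds of regions a
## microdissected tumor yields.
.delaunayEdges <- function(xy) {
  n <- nrow(xy)
  stopifnot(n >= 3L)
  ctr <- scale(xy, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1))
    return(NULL)  # collinear point set: caller falls back
  scl2 <- max(apply(xy, 2, function(v) diff(range(v))))^2
  tol <- 1e-9 * scl2
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    pi. <- xy[i, ]
    for (j in seq.int(i + 1L, n)) {
      pj <- xy[j, ]
      dirv <- pj - pi.
      m <- (pi. + pj) / 2
      u <- c(-dirv[2], dirv[1])
      others <- setdiff(seq_len(n), c(i, j))
      if (length(others) == 0L) { from <- c(from, i); to <- c(to, j); next }
      ok <- xy[others, , drop = FALSE]
      A <- (ok[, 1] - m[1])^2 + (ok[, 2] - m[2])^2 -
        sum((pi. - m)^2)
      B <- 2 * ((pi.[1] - ok[, 1]) * u[1] + (pi.[2] - ok[, 2]) * u[2])
      degen <- abs(B) <= tol
      if (any(degen & A <= tol)) next  # a collinear point blocks the circle
      lo <- suppressWarnings(max(-A[B > tol] / B[B > tol], -Inf))
      hi <- suppressWarnings(min(-A[B < -tol] / B[B < -tol], Inf))
      if (lo < hi + 1e-12 * (abs(lo) + abs(hi) + 1)) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  cbind(from, to)
}

.knnEdges <- function(xy, k) {
  n <- nrow(xy)
  stopifnot(k >= 1L, k < n)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    from <- c(from, rep.int(i, k)); to <- c(to, nb)
  }
  key <- cbind(pmin(from, to), pmax(from, to))
  keep <- !duplicated(key)
  cbind(from = key[keep, 1], to = key[keep, 2])
}

#' Build the spatial adjacency graph among regions
#'
#' Physical connections among tumor regions from their planar coordinates.
#' \code{"delaunay"} (default) takes the Delaunay triangulation edge set —
#' nearby regions are linked without a tuned radius; \code{"knn"} unions each
#' region's \code{k} nearest neighbours (symmetrised); \code{"radius"} links
#' every pair at Euclidean distance \eqn{d \le} \code{radius};
#' \code{"explicit"} takes a user-supplied undirected edge list (e.g. from
#' \code{\link{readAdjacencyList}}). A degenerate (collinear) point set under
#' \code{"delaunay"} falls back to \code{knn(k = 2)} with a warning. Edges
#' longer than the \code{pruneQuantile} distance quantile are dropped
#' (default keeps all).
#'
#' @param x a \linkS4class{TumorRegionExperiment} or a region data.frame
#'   with \code{region_id}, \code{x}, \code{y}.
#' @param method adjacency construction method.
#' @param k neighbours for \code{"knn"}.
#' @param radius distance cutoff for \code{"radius"} (> 0; may be \code{Inf}).
#' @param edgeList data.frame with columns \code{region_a}, \code{region_b}
#'   for \code{"explicit"}.
#' @param pruneQuantile keep edges with distance at or below this empirical
#'   quantile; 1 keeps all.
#' @return A \linkS4class{RegionGraph}.
#' @export
buildAdjacency <- function(x,
                           method = c("delaunay", "knn", "radius",
                                      "explicit"),
                           k = 2L, radius = NULL, edgeList = NULL,
                           pruneQuantile = 1) {
  method <- match.arg(method)
  if (is(x, "TumorRegionExperiment")) {
    ids <- regionIds(x); xy <- regionCoords(x)
  } else {
    ids <- x$region_id; xy <- cbind(x$x, x$y)
  }
  n <- length(ids)
  if (anyDuplicated(cbind(xy)) && method == "delaunay")
    stop("coincident region coordinates; Delaunay adjacency is undefined")
  em <- switch(method,
    delaunay = {
      if (n < 3L) stop("delaunay adjacency needs at least 3 regions")
      e <- .delaunayEdges(xy)
      if (is.null(e)) {
        warning("collinear coordinates; falling back to knn(k = 2)")
        method <- "knn"
        .knnEdges(xy, min(2L, n - 1L))
      } else e
    },
    knn = .knnEdges(xy, as.integer(k)),
    radius = {
      stopifnot(!is.null(radius), radius > 0)
      d <- as.matrix(dist(xy))
      idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
      cbind(from = idx[, 1], to = idx[, 2])
    },
    explicit = {
      stopifnot(is.data.frame(edgeList))
      a <- as.character(edgeList[[1]]); b <- as.character(edgeList[[2]])
      unknown <- setdiff(c(a, b), ids)
      if (length(unknown))
        stop("explicit edge references unknown region ID(s): ",
             paste(unknown, collapse = ", "))
      if (any(a == b)) stop("explicit edge list contains a self-edge")
      ia <- match(a, ids); ib <- match(b, ids)
      key <- cbind(pmin(ia, ib), pmax(ia, ib))
      keep <- !duplicated(key)
      cbind(from = key[keep, 1], to = key[keep, 2])
    })
  if (is.null(em) || nrow(em) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        distance = numeric(0))
  } else {
    dists <- sqrt(rowSums((xy[em[, 1], , drop = FALSE] -
                             xy[em[, 2], , drop = FALSE])^2))
    o <- order(em[, 1], em[, 2])
    edges <- data.frame(from = ids[em[o, 1]], to = ids[em[o, 2]],
                        distance = dists[o], stringsAsFactors = FALSE)
    if (pruneQuantile < 1) {
      cut <- quantile(edges$distance, pruneQuantile, names = FALSE)
      edges <- edges[edges$distance <= cut, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  new("RegionGraph", nodes = ids, edges = edges, method = method)
}

#' Arrange regions into ordered adjacent pairs
#'
#' Re-arranges the data by physical connections: every undirected edge
#' (i, j) contributes the two ordered rows (target = i, partner = j) and
#' (target = j, partner = i) — each region plays the target role against
#' each of its neighbours — or one row per edge with
#' \code{mode = "single"}. Phenotypes are attached from the experiment; rows
#' involving a region with missing phenotype are dropped with a message.
#'
#' @param graph a \linkS4class{RegionGraph}; its nodes must all be regions
#'   of \code{x}.
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param mode \code{"both"} (default) or \code{"single"} ordered copies per
#'   edge.
#' @return A \linkS4class{DFrame} with columns \code{target},
#'   \code{partner}, \code{distance}, \code{y_target}, \code{y_partner}.
#' @export
makeOrderedPairs <- function(graph, x, mode = c("both", "single")) {
  mode <- match.arg(mode)
  stopifnot(is(graph, "RegionGraph"), is(x, "TumorRegionExperiment"))
  if (!all(graphNodes(graph) %in% regionIds(x)))
    stop("adjacency graph names regions absent from the experiment")
  e <- graphEdges(graph)
  y <- phenotype(x)
  if (nrow(e) == 0L)
    return(DataFrame(target = character(0), partner = character(0),
                     distance = numeric(0), y_target = numeric(0),
                     y_partner = numeric(0)))
  tg <- c(e$from, if (mode == "both") e$to)
  pt <- c(e$to, if (mode == "both") e$from)
  dd <- c(e$distance, if (mode == "both") e$distance)
  ok <- is.finite(y[tg]) & is.finite(y[pt])
  if (any(!ok))
    message(sum(!ok), " ordered pair(s) dropped for missing phenotype")
  DataFrame(target = tg[ok], partner = pt[ok], distance = dd[ok],
            y_target = unname(y[tg][ok]), y_partner = unname(y[pt][ok]))
}

#' Derivative interaction traits for ordered pairs
#'
#' Turns paired fitness phenotypes \eqn{(y_1, y_2)} of target and partner
#' into the pair-level interaction trait: cooperation \eqn{z = y_1 y_2},
#' altruism \eqn{z = y_1 / y_2} (z > 1 means the target outgrows its
#' partner), competition \eqn{z = 1 / (y_1 y_2)}, or the raw target
#' phenotype (\code{kind = "phenotype"}). With
#' \code{weightByDistance = TRUE} the trait is divided by the pair distance
#' (\eqn{z_w = z / d}): nearer regions interact more strongly. Altruism and
#' competition require strictly positive phenotypes.
#'
#' @param pairs ordered-pair table from \code{\link{makeOrderedPairs}}.
#' @param kind one of "cooperation", "altruism", "competition", "phenotype".
#' @param weightByDistance divide the trait by pair distance?
#' @return \code{pairs} with added columns \code{z}, \code{z_weighted} and
#'   metadata fields \code{kind}, \code{weighted}.
#' @export
deriveTrait <- function(pairs,
                        kind = c("cooperation", "altruism", "competition",
                                 "phenotype"),
                        weightByDistance = TRUE) {
  kind <- match.arg(kind)
  y1 <- pairs$y_target; y2 <- pairs$y_partner
  if (kind %in% c("altruism", "competition")) {
    bad <- which(y1 <= 0 | y2 <= 0)
    if (length(bad))
      stop("nonpositive phenotype for region(s) ",
           paste(unique(c(pairs$target[bad][pairs$y_target[bad] <= 0],
                          pairs$partner[bad][pairs$y_partner[bad] <= 0])),
                 collapse = ", "),
           "; ", kind, " trait is undefined")
  }
  z <- switch(kind,
              cooperation = y1 * y2,
              altruism = y1 / y2,
              competition = 1 / (y1 * y2),
              phenotype = y1)
  weighted <- weightByDistance && kind != "phenotype"
  if (weighted && nrow(pairs) && any(pairs$distance <= 0))
    stop("distance weighting requires strictly positive pair distances")
  pairs$z <- z
  pairs$z_weighted <- if (weighted) z / pairs$distance else z
  metadata(pairs)$kind <- kind
  metadata(pairs)$weighted <- weighted
  pairs
}

#' Write an ordered-pair trait table
#'
#' @param pairs output of \code{\link{deriveTrait}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePairTable <- function(pairs, path) {
  df <- as.data.frame(pairs)
  df$kind <- metadata(pairs)$kind
  names(df)[names(df) == "distance"] <- "distance"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(df[, c("target", "partner", "distance", "y_target",
                     "y_partner", "z", "z_weighted", "kind")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
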