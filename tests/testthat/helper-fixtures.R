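suppressPackageStartupMessages(library(S4Vectors))

## Small deterministic dataset: 4 regions on a unit square (slightly
## perturbed so no distances tie), 3 loci.
toyRegions <- function() {
  data.frame(region_id = c("r1", "r2", "r3", "r4"),
             x = c(0, 1, 1.05, 0.02),
             y = c(0, 0.01, 1, 1.1),
             quadrant = c("A", "A", "B", "B"),
             phenotype = c(2, 3, 4, 5),
             stringsAsFactors = FALSE)
}

toyGenotypes <- function() {
  g <- matrix(c(0L, 1L, 0L, 1L,
                1L, 1L, 0L, 0L,
                0L, 0L, 1L, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"),
                              c("r1", "r2", "r3", "r4")))
  attr(g, "chrom") <- c("1", "2", "2")
  g
}

toyExperiment <- function() {
  TumorRegionExperiment(toyGenotypes(), toyRegions())
}

## Independent likelihood oracle: zooming dense grid search over the
## combination means and the (log) variance of the Gaussian model; never
## uses the closed-form estimators.
gridFitLogLik <- function(z, combination, stages = 4L, gridN = 41L) {
  ok <- !is.na(combination)
  z <- z[ok]
  lab <- as.character(combination[ok])
  groups <- split(z, lab)
  n <- length(z)
  muLo <- vapply(groups, function(g) min(z), numeric(1))
  muHi <- vapply(groups, function(g) max(z), numeric(1))
  s2Lo <- 1e-6 * max(diff(range(z))^2, 1e-8)
  s2Hi <- 4 * max(diff(range(z))^2, 1e-8)
  best <- NULL
  for (s in seq_len(stages)) {
    s2Grid <- exp(seq(log(s2Lo), log(s2Hi), length.out = gridN))
    muGrid <- lapply(seq_along(groups), function(i)
      seq(muLo[i], muHi[i], length.out = gridN))
    ## for fixed sigma^2 the likelihood separates over group means, so each
    ## group mean is grid-optimised by its own SSE
    sseBest <- vapply(seq_along(groups), function(i) {
      sse <- vapply(muGrid[[i]], function(m) sum((groups[[i]] - m)^2),
                    numeric(1))
      c(min(sse), muGrid[[i]][which.min(sse)])
    }, numeric(2))
    sseTot <- sum(sseBest[1, ])
    ll <- -n / 2 * log(2 * pi * s2Grid) - sseTot / (2 * s2Grid)
    iBest <- which.max(ll)
    best <- list(logLik = ll[iBest], s2 = s2Grid[iBest], mu = sseBest[2, ])
    ## zoom every grid around its optimum
    step <- vapply(muGrid, function(g) diff(g[1:2]), numeric(1))
    muLo <- best$mu - 2 * step
    muHi <- best$mu + 2 * step
    ratio <- s2Grid[2] / s2Grid[1]
    s2Lo <- best$s2 / ratio^2
    s2Hi <- best$s2 * ratio^2
  }
  best$logLik
}

## Brute-force Delaunay oracle: collect edges of every triangle whose
## circumcircle contains no other point (O(n^4); tiny point sets only).
bruteDelaunayEdges <- function(xy) {
  n <- nrow(xy)
  circum <- function(a, b, c) {
    ax <- xy[a, 1]; ay <- xy[a, 2]
    bx <- xy[b, 1]; by <- xy[b, 2]
    cx <- xy[c, 1]; cy <- xy[c, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  edges <- matrix(integer(0), ncol = 2)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    cr <- circum(a, b, cc)
    if (is.null(cr)) next
    others <- setdiff(seq_len(n), c(a, b, cc))
    dd <- sqrt((xy[others, 1] - cr[1])^2 + (xy[others, 2] - cr[2])^2)
    if (all(dd > cr[3] - 1e-9))
      edges <- rbind(edges, c(a, b), c(a, cc), c(b, cc))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edgeKey <- function(graph) {
  e <- graphEdges(graph)
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}
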