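## Intratumoral GWAS: per-locus Gaussian likelihood over the four ordered
## genotype combinations of adjacent region pairs, LR testing and
## genome-wide permutation thresholds.

.COMBOS <- c("GG", "GT", "TG", "TT")

## Variance floor guarding degenerate log-likelihoods (all trait values
## equal within a combination): 1e-12 x (trait range)^2.
.varFloor <- function(z) {
  r <- if (length(z)) diff(range(z)) else 0
  max(1e-12 * r^2, 1e-300)
}

#' Filter to segregating loci
#'
#' Retains loci that segregate among the non-missing regions: at least
#' \code{minMinorCount} regions carry the mutant allele and at least one
#' carries the wild-type. Somatic mutations are rare, so the mutant allele
#' is the minor one; a locus where (almost) every region carries the same
#' allele supports no combination contrast. Row order is preserved. The
#' default of 2 avoids fits dominated by a single mutant region.
#'
#' @param x a \linkS4class{TumorRegionExperiment} or a genotype matrix.
#' @param minMinorCount minimum minor-allele count (>= 1).
#' @param ... unused.
#' @return The input subset to segregating loci (with a warning when none
#'   remain).
#' @rdname filterSegregating
#' @export
setMethod("filterSegregating", "TumorRegionExperiment",
          function(x, minMinorCount = 2L, ...) {
  keep <- .segregatingMask(genotypeCalls(x), minMinorCount)
  if (!any(keep)) warning("no segregating loci remain")
  x[keep, ]
})

#' @rdname filterSegregating
#' @export
setMethod("filterSegregating", "matrix",
          function(x, minMinorCount = 2L, ...) {
  keep <- .segregatingMask(x, minMinorCount)
  if (!any(keep)) warning("no segregating loci remain")
  out <- x[keep, , drop = FALSE]
  attr(out, "chrom") <- attr(x, "chrom")[keep]
  out
})

.segregatingMask <- function(g, minMinorCount) {
  stopifnot(minMinorCount >= 1L)
  ones <- rowSums(g == 1L, na.rm = TRUE)
  zeros <- rowSums(g == 0L, na.rm = TRUE)
  ones >= minMinorCount & zeros >= 1L
}

#' Assign ordered pairs to genotype combinations at one locus
#'
#' Each ordered pair (target, partner) falls into one of the four mutation
#' combinations GG, GT, TG, TT — first letter the target's allele, second
#' the partner's (G = wild-type, T = mutant). Pairs with a missing call at
#' either member are excluded and counted.
#'
#' @param pairs ordered-pair table from \code{\link{makeOrderedPairs}}.
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param locus locus ID present in \code{x}.
#' @return factor of combination labels (levels GG, GT, TG, TT; NA =
#'   excluded) with attributes \code{counts} (named combination counts) and
#'   \code{nExcluded}.
#' @export
assignCombinations <- function(pairs, x, locus) {
  if (!locus %in% lociIds(x))
    stop("unknown locus: ", locus)
  g <- genotypeCalls(x)[locus, ]
  gt <- g[pairs$target]; gp <- g[pairs$partner]
  code <- 2L * gt + gp
  lab <- factor(.COMBOS[code + 1L], levels = .COMBOS)
  counts <- table(lab)
  structure(lab, counts = setNames(as.integer(counts), names(counts)),
            nExcluded = sum(is.na(code)))
}

#' Gaussian fit of combination means for one locus
#'
#' Alternative model: one mean per non-empty combination with a common
#' (pooled, maximum-likelihood, divisor n) variance. Null model: a single
#' grand mean and the total variance. The variance is clamped to a floor of
#' \code{1e-12 * range(z)^2}; the log-likelihood is the Gaussian
#' log-likelihood at the estimates.
#'
#' @param z numeric derivative-trait values, one per ordered pair.
#' @param combination combination labels as from
#'   \code{\link{assignCombinations}} (NA entries are dropped).
#' @param model "alternative" or "null".
#' @param varFloor optional variance floor override.
#' @return A \linkS4class{LocusFit}.
#' @export
fitLocus <- function(z, combination, model = c("alternative", "null"),
                     varFloor = NULL) {
  model <- match.arg(model)
  ok <- !is.na(combination) & !is.na(z)
  z <- z[ok]; combination <- droplevels(factor(combination[ok]))
  n <- length(z)
  if (n < 2L) stop("at least 2 observations are required")
  if (is.null(varFloor)) varFloor <- .varFloor(z)
  if (model == "alternative") {
    mu <- vapply(split(z, combination), mean, numeric(1))
    res <- z - mu[as.character(combination)]
    k <- length(mu)
  } else {
    mu <- c(mean = mean(z))
    res <- z - mu
    k <- 1L
  }
  s2 <- sum(res^2) / n
  if (s2 < varFloor) {
    warning("variance clamped to floor (degenerate trait values)")
    s2 <- varFloor
  }
  ll <- -n / 2 * log(2 * pi * s2) - sum(res^2) / (2 * s2)
  new("LocusFit", mu = mu, sigma2 = s2, logLik = ll, k = as.integer(k),
      n = as.integer(n), model = model)
}

#' Likelihood-ratio statistic of nested locus fits
#'
#' \eqn{LR = 2(\ln L_{alt} - \ln L_{null})}; with profiled Gaussian MLEs
#' this equals \eqn{n \ln(\hat\sigma^2_{null} / \hat\sigma^2_{alt})}.
#' Both fits must be computed on the same observations.
#'
#' @param fitAlt alternative-model \linkS4class{LocusFit}.
#' @param fitNull null-model \linkS4class{LocusFit}.
#' @return Nonnegative LR value.
#' @export
lrStatistic <- function(fitAlt, fitNull) {
  stopifnot(is(fitAlt, "LocusFit"), is(fitNull, "LocusFit"))
  if (fitAlt@n != fitNull@n)
    stop("fits were computed on different observation counts")
  max(0, 2 * (fitAlt@logLik - fitNull@logLik))
}

## Shared scan core: observed per-locus LR plus permutation maxima.
## Permutations shuffle whole genotype columns (region profiles) across
## regions, preserving between-locus co-occurrence while phenotypes,
## coordinates and adjacency stay fixed.
.gwasScan <- function(x, pairs, z, nPerm, seed) {
  g <- genotypeCalls(x)
  R <- ncol(g)
  if (metadata(pairs)$kind == "phenotype" && nrow(pairs) == 0)
    stop("empty pair table")
  tidx <- match(pairs$target, colnames(g))
  pidx <- match(pairs$partner, colnames(g))
  vf <- .varFloor(z)
  gt <- t(g)
  obs <- lr_scan_cpp(gt, tidx, pidx, z, matrix(seq_len(R), nrow = 1),
                     vf)[1, ]
  maxima <- numeric(0)
  if (nPerm >= 1) {
    set.seed(childSeed(seed, "permutation"))
    perms <- t(vapply(seq_len(nPerm), function(i) sample.int(R),
                      integer(R)))
    lrm <- lr_scan_cpp(gt, tidx, pidx, z, perms, vf)
    maxima <- apply(lrm, 1, max)
  }
  list(obs = setNames(obs, rownames(g)), maxima = maxima)
}

## Units entering the likelihood for a given trait: ordered region pairs
## for derivative traits, or the regions themselves for the unpaired
## per-region phenotype scan (each region "paired" with itself, collapsing
## the four combinations to the two groups GG and TT).
.traitUnits <- function(x, graph, trait, weightByDistance, orderedPairs,
                        logTransform) {
  if (trait == "phenotype") {
    ids <- regionIds(x)
    pairs <- DataFrame(target = ids, partner = ids,
                       distance = rep(1, length(ids)),
                       y_target = unname(phenotype(x)),
                       y_partner = unname(phenotype(x)))
    pairs$z <- pairs$y_target
    pairs$z_weighted <- pairs$z
    metadata(pairs)$kind <- "phenotype"
    metadata(pairs)$weighted <- FALSE
  } else {
    pairs <- deriveTrait(makeOrderedPairs(graph, x, mode = orderedPairs),
                         kind = trait,
                         weightByDistance = weightByDistance)
  }
  z <- pairs$z_weighted
  if (logTransform) {
    if (any(z <= 0))
      stop("log transform requires strictly positive trait values")
    z <- log(z)
  }
  list(pairs = pairs, z = z)
}

#' Genome-wide permutation threshold for the LR scan
#'
#' For each permutation the genotype columns (whole per-region mutation
#' profiles) are shuffled across regions while phenotypes, coordinates and
#' adjacency stay fixed; the maximum LR over all loci is recorded. The
#' threshold is the empirical \code{1 - alpha} quantile of the maxima,
#' taken as the \code{ceiling((1 - alpha) * nPerm)}-th order statistic
#' (conservative tie-breaking). The RNG is fully determined by \code{seed}.
#'
#' @param x a \linkS4class{TumorRegionExperiment} (already filtered to
#'   segregating loci).
#' @param graph a \linkS4class{RegionGraph} over the regions of \code{x}.
#' @param trait derivative trait kind (or "phenotype" for the unpaired
#'   per-region scan).
#' @param nPerm number of permutations (>= 1).
#' @param alpha genome-wide significance level in (0, 1).
#' @param seed integer seed.
#' @param weightByDistance,orderedPairs,logTransform passed to the trait
#'   construction; see \code{\link{deriveTrait}} and
#'   \code{\link{makeOrderedPairs}}.
#' @return The threshold, with the permutation maxima as attribute
#'   \code{"maxima"}.
#' @export
permutationThreshold <- function(x, graph,
                                 trait = c("cooperation", "altruism",
                                           "competition", "phenotype"),
                                 nPerm = 1000L, alpha = 0.01, seed = 1L,
                                 weightByDistance = FALSE,
                                 orderedPairs = c("both", "single"),
                                 logTransform = FALSE) {
  trait <- match.arg(trait)
  orderedPairs <- match.arg(orderedPairs)
  stopifnot(nPerm >= 1L, alpha > 0, alpha < 1)
  tu <- .traitUnits(x, graph, trait, weightByDistance, orderedPairs,
                    logTransform)
  sc <- .gwasScan(x, tu$pairs, tu$z, nPerm, seed)
  structure(.thresholdFromMaxima(sc$maxima, alpha), maxima = sc$maxima)
}

.thresholdFromMaxima <- function(maxima, alpha) {
  nPerm <- length(maxima)
  if (alpha < 1 / (nPerm + 1))
    warning("alpha = ", alpha, " is finer than ", nPerm,
            " permutations can resolve; threshold set to the maximum")
  sort(maxima)[min(nPerm, ceiling((1 - alpha) * nPerm))]
}

#' Run the intratumoral association scan
#'
#' Full per-trait workflow: segregating-locus filter, ordered-pair
#' assignment to genotype combinations, Gaussian combination-mean fits, LR
#' per locus, and significance against the genome-wide permutation
#' threshold. The variance proportion per locus is
#' \eqn{1 - \hat\sigma^2_{alt} / \hat\sigma^2_{null}}. Results are ordered
#' by chromosome label when one exists, else input order.
#'
#' @inheritParams permutationThreshold
#' @param graph adjacency graph; built with Delaunay triangulation when
#'   \code{NULL}.
#' @param minMinorCount segregating-locus filter threshold.
#' @return A \linkS4class{GwasResults} object (zero rows, with a warning,
#'   when no locus segregates).
#' @examples
#' sim <- simulateTumor(simulationConfig(nRegions = 23, nLoci = 40,
#'                                       seed = 7))
#' res <- runGwas(experiment(sim), graph = adjacency(sim), nPerm = 50,
#'                seed = 7)
#' head(res)
#' @export
runGwas <- function(x, graph = NULL,
                    trait = c("cooperation", "altruism", "competition",
                              "phenotype"),
                    nPerm = 1000L, alpha = 0.01, minMinorCount = 2L,
                    seed = 1L, weightByDistance = FALSE,
                    orderedPairs = c("both", "single"),
                    logTransform = FALSE) {
  trait <- match.arg(trait)
  orderedPairs <- match.arg(orderedPairs)
  stopifnot(is(x, "TumorRegionExperiment"))
  xs <- suppressWarnings(filterSegregating(x, minMinorCount))
  meta <- list(trait = trait, nPerm = nPerm, alpha = alpha, seed = seed,
               minMinorCount = minMinorCount,
               weightByDistance = weightByDistance,
               orderedPairs = orderedPairs, logTransform = logTransform)
  if (nrow(xs) == 0L) {
    warning("no segregating loci; empty result")
    res <- new("GwasResults", DataFrame(locus_id = character(0)))
    metadata(res) <- meta
    return(res)
  }
  if (is.null(graph) && trait != "phenotype")
    graph <- buildAdjacency(x, method = "delaunay")
  tu <- .traitUnits(xs, graph, trait, weightByDistance, orderedPairs,
                    logTransform)
  sc <- .gwasScan(xs, tu$pairs, tu$z, nPerm, seed)
  # nPerm = 0 skips thresholding (LR statistics only, nothing significant)
  thr <- if (nPerm >= 1L) .thresholdFromMaxima(sc$maxima, alpha) else Inf

  g <- genotypeCalls(xs)
  tidx <- match(tu$pairs$target, colnames(g))
  pidx <- match(tu$pairs$partner, colnames(g))
  cc <- combo_counts_cpp(t(g), tidx, pidx)
  z <- tu$z
  fits <- lapply(seq_len(nrow(g)), function(l) {
    code <- 2L * g[l, tidx] + g[l, pidx]
    lab <- factor(.COMBOS[code + 1L], levels = .COMBOS)
    if (sum(!is.na(lab)) < 2L)
      return(list(mu = setNames(rep(NA_real_, 4), .COMBOS),
                  s2a = NA_real_, s2n = NA_real_))
    fa <- suppressWarnings(fitLocus(z, lab, "alternative"))
    fn <- suppressWarnings(fitLocus(z, lab, "null"))
    mu <- setNames(rep(NA_real_, 4), .COMBOS)
    mu[names(fa@mu)] <- fa@mu
    list(mu = mu, s2a = fa@sigma2, s2n = fn@sigma2)
  })
  mus <- do.call(rbind, lapply(fits, `[[`, "mu"))
  s2a <- vapply(fits, `[[`, numeric(1), "s2a")
  s2n <- vapply(fits, `[[`, numeric(1), "s2n")
  ve <- pmin(pmax(1 - s2a / s2n, 0), 1)
  chrom <- rowData(xs)$chrom
  res <- DataFrame(locus_id = rownames(g), chrom = chrom,
                   n_GG = cc[, 1], n_GT = cc[, 2], n_TG = cc[, 3],
                   n_TT = cc[, 4],
                   mu_GG = mus[, "GG"], mu_GT = mus[, "GT"],
                   mu_TG = mus[, "TG"], mu_TT = mus[, "TT"],
                   sigma2 = s2a, LR = unname(sc$obs), threshold = thr,
                   significant = unname(sc$obs) > thr,
                   var_explained = ve,
                   row.names = rownames(g))
  if (any(!is.na(chrom)))
    res <- res[order(chrom, seq_len(nrow(res)), na.last = TRUE), ]
  out <- new("GwasResults", res)
  metadata(out) <- c(meta, list(threshold = thr, maxima = sc$maxima,
                                nPairs = nrow(tu$pairs)))
  out
}

#' Manhattan-plot table of an association scan
#'
#' @param results a \linkS4class{GwasResults}.
#' @return data.frame \code{locus_id}, \code{chrom},
#'   \code{position_index}, \code{LR}, directly consumable by standard
#'   plotting tools.
#' @export
manhattanTable <- function(results) {
  data.frame(locus_id = results$locus_id, chrom = results$chrom,
             position_index = seq_len(nrow(results)), LR = results$LR)
}

#' Write association-scan results as TSV
#'
#' @param results a \linkS4class{GwasResults}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGwasResults <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
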