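## Decomposition of a locus's effect on the pair-level trait into direct,
## indirect and across-cell epistatic components.

## Orthogonal 2x2 factorial sign coding of the four ordered combinations
## (rows GG, GT, TG, TT; first letter = target allele). "direct" contrasts
## the target's own allele, "indirect" the partner's allele, "epistatic"
## their product.
.comboSigns <- matrix(c(
  #    direct indirect epistatic
  1,  1,  1,   # GG
  1, -1, -1,   # GT
  -1,  1, -1,  # TG
  -1, -1,  1   # TT
), nrow = 4, byrow = TRUE,
dimnames = list(c("GG", "GT", "TG", "TT"),
                c("direct", "indirect", "epistatic")))

#' Decompose combination means into direct, indirect and epistatic effects
#'
#' Orthogonal factorial contrasts with quarter normalisation:
#' \deqn{\mu_0 = (\mu_{GG}+\mu_{GT}+\mu_{TG}+\mu_{TT})/4}
#' \deqn{a_d = ((\mu_{GG}+\mu_{GT}) - (\mu_{TG}+\mu_{TT}))/4}
#' \deqn{a_i = ((\mu_{GG}+\mu_{TG}) - (\mu_{GT}+\mu_{TT}))/4}
#' \deqn{a_e = ((\mu_{GG}+\mu_{TT}) - (\mu_{GT}+\mu_{TG}))/4}
#' The direct effect contrasts the target region's own allele, the indirect
#' effect the partner's allele, and the across-cell epistatic effect their
#' interaction. The map is exactly invertible
#' (\code{\link{reconstructMeans}}): \eqn{\mu_c = \mu_0 \pm a_d \pm a_i \pm
#' a_e}. All four combinations must be estimable. Sign convention: the
#' wild-type (G) side of each contrast is positive, so a negative
#' \code{a_direct} means the mutant target allele raises the trait.
#'
#' @param mu numeric(4), combination means named (or ordered) GG, GT, TG,
#'   TT.
#' @return Named numeric: \code{mu0}, \code{a_direct}, \code{a_indirect},
#'   \code{a_epistatic}.
#' @examples
#' decomposeEffects(c(GG = 4, GT = 2, TG = 2, TT = 0))
#' @export
decomposeEffects <- function(mu) {
  if (is.null(names(mu))) names(mu) <- rownames(.comboSigns)
  if (!all(rownames(.comboSigns) %in% names(mu)) ||
      any(!is.finite(mu[rownames(.comboSigns)])))
    stop("locus is not decomposable: all four combination means ",
         "(GG, GT, TG, TT) must be available")
  mu <- mu[rownames(.comboSigns)]
  c(mu0 = mean(mu),
    a_direct = sum(.comboSigns[, "direct"] * mu) / 4,
    a_indirect = sum(.comboSigns[, "indirect"] * mu) / 4,
    a_epistatic = sum(.comboSigns[, "epistatic"] * mu) / 4)
}

#' Inverse of \code{\link{decomposeEffects}}
#'
#' @param effects named numeric with \code{mu0}, \code{a_direct},
#'   \code{a_indirect}, \code{a_epistatic}.
#' @return Named numeric(4) of combination means (GG, GT, TG, TT).
#' @export
reconstructMeans <- function(effects) {
  a <- effects[c("a_direct", "a_indirect", "a_epistatic")]
  setNames(effects[["mu0"]] + as.numeric(.comboSigns %*% a),
           rownames(.comboSigns))
}

## Single-effect LRs under a fixed full-model variance. Means are re-fitted
## under the linear constraint that the named contrast is zero; sigma^2 is
## held at the full (cell-means) MLE so the three single-degree statistics
## are exactly additive and sum to the omnibus under balanced counts:
## LR_e = (SSE_constrained - SSE_full) / sigma2_full.
.effectLR <- function(z, combination,
                      effect = c("direct", "indirect", "epistatic",
                                 "omnibus")) {
  effect <- match.arg(effect)
  ok <- !is.na(combination) & !is.na(z)
  z <- z[ok]
  lab <- as.character(combination[ok])
  n <- length(z)
  if (n < 2L) stop("at least 2 observations are required")
  S <- .comboSigns[lab, , drop = FALSE]
  Xfull <- cbind(1, S)
  sseOf <- function(X) {
    f <- lm.fit(X, z)
    sum(f$residuals^2)
  }
  sseF <- sseOf(Xfull)
  s2f <- max(sseF / n, .varFloor(z))
  Xc <- if (effect == "omnibus") Xfull[, 1, drop = FALSE]
        else Xfull[, c(1L, 1L + which(colnames(S) != effect)),
                   drop = FALSE]
  max(0, (sseOf(Xc) - sseF) / s2f)
}

#' Likelihood-ratio test of one decomposed effect
#'
#' Tests whether the direct, indirect or across-cell epistatic contrast of a
#' locus is zero on the pair-level trait. The constrained Gaussian fit
#' re-estimates the remaining means under the linear constraint; the
#' variance is held at the full-model estimate, which keeps the three
#' single-effect statistics mutually orthogonal (they sum to the omnibus
#' statistic under balanced combination counts). Significance comes from
#' permutation of whole genotype columns, as in the genome-wide scan.
#'
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param graph a \linkS4class{RegionGraph}.
#' @param locus locus ID; must have all four combinations non-empty.
#' @param effect "direct", "indirect", "epistatic" or "omnibus".
#' @param trait derivative trait kind.
#' @param nPerm permutations for the p-value (0 = statistic only).
#' @param seed integer seed.
#' @param weightByDistance,orderedPairs see \code{\link{deriveTrait}} and
#'   \code{\link{makeOrderedPairs}}.
#' @return list with \code{LR}, \code{pvalue} (NA when \code{nPerm} = 0),
#'   \code{nPerm} and \code{permLR} (the permutation null LR values).
#' @export
testEffect <- function(x, graph, locus,
                       effect = c("direct", "indirect", "epistatic",
                                  "omnibus"),
                       trait = c("cooperation", "altruism", "competition",
                                 "phenotype"),
                       nPerm = 1000L, seed = 1L, weightByDistance = FALSE,
                       orderedPairs = c("both", "single")) {
  effect <- match.arg(effect)
  trait <- match.arg(trait)
  orderedPairs <- match.arg(orderedPairs)
  pairs <- deriveTrait(makeOrderedPairs(graph, x, mode = orderedPairs),
                       kind = trait, weightByDistance = weightByDistance)
  z <- pairs$z_weighted
  combo <- assignCombinations(pairs, x, locus)
  if (any(attr(combo, "counts") == 0L))
    stop("locus ", locus, " is not decomposable: empty combination(s) ",
         paste(names(which(attr(combo, "counts") == 0L)), collapse = ", "))
  obs <- .effectLR(z, combo, effect)
  pval <- NA_real_
  permLR <- numeric(0)
  if (nPerm >= 1L) {
    g <- genotypeCalls(x)[locus, ]
    tidx <- match(pairs$target, names(g))
    pidx <- match(pairs$partner, names(g))
    set.seed(childSeed(seed, paste0("effect-", effect)))
    permLR <- vapply(seq_len(nPerm), function(b) {
      perm <- sample.int(length(g))
      gp <- g[perm]
      code <- 2L * gp[tidx] + gp[pidx]
      lab <- factor(.COMBOS[code + 1L], levels = .COMBOS)
      tryCatch(.effectLR(z, lab, effect), error = function(e) 0)
    }, numeric(1))
    pval <- (1 + sum(permLR >= obs)) / (nPerm + 1)
  }
  list(LR = obs, pvalue = pval, nPerm = nPerm, permLR = permLR)
}

#' Variance proportions of the decomposed effects
#'
#' Component variances under the equal-frequency contrast convention are
#' \eqn{V_x = a_x^2}; proportions are \eqn{p_x = V_x / (V_d + V_i + V_e)}.
#' With \code{weighted = TRUE} and observed combination counts, components
#' are instead sequential weighted sums of squares (order direct, indirect,
#' epistatic) on the cell means. All-zero effects give an NA triple with a
#' warning.
#'
#' @param effects output of \code{\link{decomposeEffects}}.
#' @param counts named combination counts (needed when
#'   \code{weighted = TRUE}).
#' @param weighted use observed-frequency sequential sums of squares?
#' @return Named numeric: \code{p_direct}, \code{p_indirect},
#'   \code{p_epistatic}; invariant to shifting all four means by a constant
#'   and to joint rescaling.
#' @export
varianceProportions <- function(effects, counts = NULL, weighted = FALSE) {
  a <- effects[c("a_direct", "a_indirect", "a_epistatic")]
  nm <- c("p_direct", "p_indirect", "p_epistatic")
  if (!weighted) {
    v <- a^2
    if (sum(v) == 0) {
      warning("all effects are zero; variance proportions undefined")
      return(setNames(rep(NA_real_, 3), nm))
    }
    return(setNames(as.numeric(v / sum(v)), nm))
  }
  stopifnot(!is.null(counts))
  counts <- counts[rownames(.comboSigns)]
  mu <- reconstructMeans(effects)
  w <- as.numeric(counts)
  ss <- numeric(3)
  X <- cbind(1)
  Xall <- cbind(1, .comboSigns)
  prev <- sum(w * (mu - sum(w * mu) / sum(w))^2)
  for (i in 1:3) {
    Xi <- Xall[, seq_len(i + 1), drop = FALSE]
    f <- lm.wfit(Xi, as.numeric(mu), w)
    cur <- sum(w * f$residuals^2)
    ss[i] <- prev - cur
    prev <- cur
  }
  if (sum(ss) <= 0) {
    warning("all effects are zero; variance proportions undefined")
    return(setNames(rep(NA_real_, 3), nm))
  }
  setNames(ss / sum(ss), nm)
}

#' Decompose every (significant) locus of a scan
#'
#' For each requested locus with all four combinations populated: contrast
#' estimates, per-effect LR statistics (fixed full-model variance
#' convention) and variance proportions. Non-decomposable loci are reported
#' with NA effects.
#'
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param graph a \linkS4class{RegionGraph}.
#' @param results optional \linkS4class{GwasResults}; defaults to its
#'   significant loci when \code{loci} is NULL.
#' @param loci explicit locus IDs (overrides \code{results}).
#' @param trait derivative trait kind.
#' @param weightByDistance,orderedPairs see \code{\link{deriveTrait}}.
#' @return \linkS4class{DFrame} with columns \code{locus_id},
#'   \code{trait_kind}, \code{mu0}, \code{a_direct}, \code{a_indirect},
#'   \code{a_epistatic}, \code{LR_direct}, \code{LR_indirect},
#'   \code{LR_epistatic}, \code{p_direct}, \code{p_indirect},
#'   \code{p_epistatic} (the \code{p_*} columns are variance proportions).
#' @export
decomposeLoci <- function(x, graph, results = NULL, loci = NULL,
                          trait = c("cooperation", "altruism",
                                    "competition", "phenotype"),
                          weightByDistance = FALSE,
                          orderedPairs = c("both", "single")) {
  trait <- match.arg(trait)
  orderedPairs <- match.arg(orderedPairs)
  if (is.null(loci)) {
    stopifnot(!is.null(results))
    loci <- results$locus_id[results$significant]
  }
  pairs <- deriveTrait(makeOrderedPairs(graph, x, mode = orderedPairs),
                       kind = trait, weightByDistance = weightByDistance)
  z <- pairs$z_weighted
  rows <- lapply(loci, function(loc) {
    combo <- assignCombinations(pairs, x, loc)
    counts <- attr(combo, "counts")
    if (any(counts == 0L))
      return(DataFrame(locus_id = loc, trait_kind = trait, mu0 = NA_real_,
                       a_direct = NA_real_, a_indirect = NA_real_,
                       a_epistatic = NA_real_, LR_direct = NA_real_,
                       LR_indirect = NA_real_, LR_epistatic = NA_real_,
                       p_direct = NA_real_, p_indirect = NA_real_,
                       p_epistatic = NA_real_))
    mu <- vapply(split(z[!is.na(combo)], droplevels(combo[!is.na(combo)])),
                 mean, numeric(1))
    eff <- decomposeEffects(mu)
    pr <- suppressWarnings(varianceProportions(eff))
    DataFrame(locus_id = loc, trait_kind = trait, mu0 = eff[["mu0"]],
              a_direct = eff[["a_direct"]],
              a_indirect = eff[["a_indirect"]],
              a_epistatic = eff[["a_epistatic"]],
              LR_direct = .effectLR(z, combo, "direct"),
              LR_indirect = .effectLR(z, combo, "indirect"),
              LR_epistatic = .effectLR(z, combo, "epistatic"),
              p_direct = pr[["p_direct"]],
              p_indirect = pr[["p_indirect"]],
              p_epistatic = pr[["p_epistatic"]])
  })
  if (length(rows) == 0L)
    return(DataFrame(locus_id = character(0)))
  do.call(rbind, rows)
}

#' Per-locus social-effects regression on region phenotypes
#'
#' Estimates the direct, indirect and across-cell epistatic effect of each
#' locus on the region-level phenotype by ordinary least squares of
#' \eqn{y_i} on the region's own allele \eqn{g_i}, the mean allele of its
#' adjacent neighbours \eqn{\bar g_{N(i)}}, and their product — the same
#' design the synthetic-tumor generator uses, so planted architectures are
#' recovered on their own scale. Regions with a missing call at the locus
#' are dropped; neighbour means ignore missing neighbours.
#'
#' @param x a \linkS4class{TumorRegionExperiment}.
#' @param graph a \linkS4class{RegionGraph}.
#' @param loci locus IDs (default: all loci of \code{x}).
#' @return \linkS4class{DFrame}: \code{locus_id}, \code{a_direct},
#'   \code{a_indirect}, \code{a_epistatic} (NA when the design is
#'   collinear, e.g. a non-segregating locus).
#' @export
estimateSocialEffects <- function(x, graph, loci = NULL) {
  if (is.null(loci)) loci <- lociIds(x)
  g <- genotypeCalls(x)
  y <- phenotype(x)
  ids <- regionIds(x)
  e <- graphEdges(graph)
  nbr <- lapply(setNames(ids, ids), function(i)
    c(e$to[e$from == i], e$from[e$to == i]))
  est <- vapply(loci, function(loc) {
    gi <- g[loc, ]
    nbar <- vapply(ids, function(i) {
      v <- gi[nbr[[i]]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    keep <- !is.na(gi) & !is.na(nbar)
    X <- cbind(1, gi[keep], nbar[keep], gi[keep] * nbar[keep])
    if (qr(X)$rank < 4L) return(rep(NA_real_, 3))
    lm.fit(X, y[ids][keep])$coefficients[2:4]
  }, numeric(3))
  DataFrame(locus_id = loci, a_direct = est[1, ], a_indirect = est[2, ],
            a_epistatic = est[3, ], row.names = loci)
}

#' Write a decomposition table as TSV
#'
#' @param decomposition output of \code{\link{decomposeLoci}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDecomposition <- function(decomposition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(as.data.frame(decomposition), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
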