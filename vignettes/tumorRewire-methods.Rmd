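---
title: "Rewiring intratumoral interaction networks: model and methods"
author: "tumorRewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rewiring intratumoral interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorRewire)
library(S4Vectors)
```

## The problem

A tumor is an ecosystem of genetically distinct cell populations that
cooperate and compete across space. Ordinary single-cell or region-level
association studies link a somatic mutation to a region's own phenotype and
stop there; they are silent about how a mutation in one region changes the
fitness of its *neighbours*, and about the joint, game-like structure of
those interactions. `tumorRewire` models exactly that: spatially adjacent
tumor regions are treated as interacting players, pair-level interaction
traits are built from their fitness phenotypes, and a per-locus likelihood
over the ordered genotype combinations of each pair tests whether a
mutation rewires cooperation, altruism or competition within the tumor.

The data the package expects are modest and typical of multi-region
microdissection studies: tens of regions with planar coordinates and one
fitness-related phenotype each (ploidy level is the canonical choice), and
a binary somatic-mutation matrix (wild-type/mutant) over hundreds of loci.

## Pairing regions and derivative traits

Regions are wired by a spatial adjacency graph. The default is the
Delaunay triangulation — it reproduces "physical neighbourhood" on an
irregular microdissection layout without a tuned radius parameter — with
k-nearest-neighbour, fixed-radius and explicit edge-list alternatives. The
Delaunay edge set is computed directly from the empty-circumcircle
characterisation (an edge is Delaunay exactly when some circle through its
two endpoints contains no other region), an $O(n^3)$ vectorised test that
is ample at this problem scale and is validated in the test suite against
a brute-force triangle-enumeration oracle and the minimum-spanning-tree
subset property.

Every undirected edge $(i, j)$ yields two ordered pairs: each region in
turn plays the *target* role against its *partner*. For phenotypes
$y_1$ (target) and $y_2$ (partner) the derivative interaction traits are

* cooperation: $z = y_1 y_2$ — large when both partners prosper together;
* altruism: $z = y_1 / y_2$ — the direction convention is
  target-over-partner, so $z > 1$ means the target outgrows its partner;
* competition: $z = 1 / (y_1 y_2)$ — the exact inverse of cooperation.

Ratio and inverse traits require strictly positive phenotypes, which the
data model enforces. Two identities are asserted package-wide on
randomised inputs: competition $\times$ cooperation $= 1$ per pair, and
altruism reciprocity $z_{ij} \cdot z_{ji} = 1$.

Distance weighting ($z_w = z/d$, nearer pairs interacting more strongly)
is used for network edge scores, where interaction strength between
regions is the quantity of interest. The association scan fits the *raw*
derivative variable by default: the likelihood below is a model for the
interaction trait itself, and folding the fixed geometry into the response
only inflates the within-combination variance (the flag
`weightByDistance` switches either behaviour).

## The per-locus likelihood

At a biallelic locus each ordered pair falls into one of four mutation
combinations $GG, GT, TG, TT$ (first letter = target's allele, G =
wild-type, T = mutant). With $n_c$ pairs in combination $c$ the model for
the trait is Gaussian with one mean per combination and a common variance:

$$L_{alt} = \prod_{c} \prod_{i=1}^{n_c} N(z_i \mid \mu_c, \sigma^2),
\qquad
L_{null} = \prod_{i} N(z_i \mid \mu, \sigma^2).$$

The single shared $\sigma^2$ follows the model's homoscedastic reading
(one variance, combination-specific means). Maximum-likelihood estimates
are closed-form (combination means; pooled variance with divisor $n$), and
the statistic is $LR = 2(\ln L_{alt} - \ln L_{null}) =
n\ln(\hat\sigma^2_{null}/\hat\sigma^2_{alt})$. The test suite checks the
closed forms against an independent zooming grid-search maximiser to
$10^{-6}$ in log-likelihood, and the worked four-observation example with
$LR = 4\ln 5$ to $10^{-9}$.

Numerical choices: the variance is clamped to a floor of
$10^{-12}\,(\mathrm{range}\,z)^2$ so degenerate traits (all values equal)
produce $LR = 0$ rather than infinities; empty combinations are simply
dropped from the alternative fit, so the effective dimension per locus is
(number of non-empty combinations $-$ 1); pairs with a missing call at
either member are excluded per locus; loci enter the scan only if they
segregate (at least `minMinorCount = 2` mutant regions and one wild-type
region — a single mutant region pins two of the four combinations to one
observation and the fit degenerates).

## Genome-wide significance by permutation

Because each edge contributes two ordered, overlapping observations, the
usual $\chi^2$ reference for $LR$ is wrong, and combination dimensions
vary across loci. Both problems are handled at once by a
maximum-statistic permutation null: whole genotype *columns* (per-region
mutation profiles) are shuffled across regions — preserving
between-locus co-occurrence — while phenotypes, coordinates and the
adjacency stay fixed; the maximum $LR$ over all loci is recorded per
permutation, and the genome-wide threshold at level $\alpha$ is the
$\lceil(1-\alpha)\,n_{perm}\rceil$-th order statistic of the maxima
(conservative tie-breaking), with significance declared for $LR$ strictly
above it. Under exchangeability the implied family-wise rejection
probability at $\alpha = 0.01$ with 1,000 permutations is $11/1001
\approx 1.1\%$.

The package ships this guarantee as an experiment:
`fwerCalibration()` draws null tumors (genotypes independent of the
phenotype; 23 regions on a Delaunay adjacency, 50 segregating loci), runs
the full cooperation-trait scan on each, and reports the fraction of
replicates with any significant locus. At 200 replicates and 1,000
permutations this runs in about a minute and is asserted (binomial 95%
band) in the acceptance tests; `scripts/acceptance.R` reports the same
number.

An unpaired mode (`trait = "phenotype"`) applies the identical machinery
to the regions themselves, with the two groups G and T — useful as the
plain per-region GWAS counterpart of the paired scan, and the two modes
rank a purely direct-effect causal locus first equally often in the test
suite's simulations.

## Decomposing a locus's effect

For a decomposable locus (all four combinations observed), the
combination means are re-expressed through orthogonal $2 \times 2$
factorial contrasts with quarter normalisation:

$$\mu_0 = \tfrac14(\mu_{GG}+\mu_{GT}+\mu_{TG}+\mu_{TT}), \quad
a_d = \tfrac14\big((\mu_{GG}+\mu_{GT})-(\mu_{TG}+\mu_{TT})\big),$$
$$a_i = \tfrac14\big((\mu_{GG}+\mu_{TG})-(\mu_{GT}+\mu_{TT})\big), \quad
a_e = \tfrac14\big((\mu_{GG}+\mu_{TT})-(\mu_{GT}+\mu_{TG})\big),$$

so the *direct* effect $a_d$ contrasts the target's own allele, the
*indirect* effect $a_i$ the partner's allele, and the *across-cell
epistatic* effect $a_e$ their interaction. The source framework defers the
explicit decomposition formulas to its quantitative-genetic antecedents;
these contrasts are the package's choice because they uniquely satisfy the
verbal definitions and are exactly invertible
($\mu_c = \mu_0 \pm a_d \pm a_i \pm a_e$), which the tests assert to
machine precision.

Each effect is tested by a constrained fit: the means are re-estimated
under the linear constraint that the named contrast is zero, and
$LR_{effect} = (SSE_{constrained} - SSE_{full})/\hat\sigma^2_{full}$ with
the variance held at the full-model estimate. Holding $\sigma^2$ fixed is
a deliberate deviation from re-profiling it in both fits: it makes the
three single-degree statistics mutually orthogonal, summing exactly to the
omnibus statistic under balanced combination counts, so the decomposition
of evidence mirrors the decomposition of means. Significance again comes
from genotype-column permutation. Variance proportions default to the
equal-frequency contrast convention $p_x = a_x^2/(a_d^2+a_i^2+a_e^2)$ —
with two dozen regions the observed combination frequencies are too noisy
to anchor a frequency-weighted partition, though one (sequential weighted
sums of squares) is available behind `weighted = TRUE`. Published
variance-share figures from other datasets may follow a different
bookkeeping; the convention here is documented rather than matched.

### Two scales: pair-level contrasts vs region-level architecture

The synthetic generator (below) plants effects on the *region phenotype*
with neighbour-averaged indirect and epistatic terms, while
`decomposeEffects()` works on *pair-level* combination means. The two
scales differ by a degree-dependent attenuation (a pair conditions on one
neighbour out of several) and by the factorial sign/normalisation
convention, so pair-level contrasts are not unbiased estimates of planted
region-level coefficients — nor should they be. For recovery of a planted
architecture the package provides `estimateSocialEffects()`: per-locus
ordinary least squares of the phenotype on (own allele, neighbour-mean
allele, their product), the generator's own design, which is unbiased by
construction and is what `truthRecoveryReport()` and the acceptance
recovery experiment use. Pair-level decompositions are reported on their
own (documented) scale.

## Interaction networks

For each undirected edge the cooperation score is $y_i y_j / d_{ij}$ and
the competition score $1/(y_i y_j d_{ij})$ — here distance weighting is
always on, since edge strength should decay with separation; the two
scores multiply to $1/d^2$, asserted per edge. A network keeps the edges
at or above the `edgeQuantile` (default 0.8) empirical quantile of its
kind's scores; using one shared quantile for both networks makes any
density contrast between cooperative and competitive wiring attributable
to the score distributions themselves. Cooperation edges are mutual
activations; competition edges are drawn as inhibition of the
lower-phenotype member by the higher-phenotype member, the direction the
altruism ratio indicates. Hubs are degree-ranked regions (ties broken
lexicographically) — "connected with the most other regions" is the
operative notion, so degree rather than betweenness.

Each adjacent pair is also classified into the ecological strategy
matrix. The source narrative never specifies how a $+/0/-$ strategy is
measured from data; the package's rule is quantile-based with one
transparent parameter: a region plays $+$ above the $0.5 +$
`neutralBand` cohort phenotype quantile, $-$ below $0.5 -$
`neutralBand`, else $0$ (default band 0.1, i.e. the middle 20% is
neutral). The ordered sign couple addresses the matrix — mutualism
$(+/+)$, commensalism $(+/0, 0/+)$, predation/parasitism $(+/-)$,
coexistence $(0/0)$, amensalism $(0/-, -/0)$, antagonism $(-/-)$ — which
reproduces the qualitative reading of large-large adjacency as
cooperation, small-small as conflict and large-small as parasitism. An
exhaustive sweep of the nine sign couples onto the six labels, with
symmetry, is part of the acceptance tests.

## The synthetic-tumor generator

`simulateTumor()` exists so every stage is testable with known truth.
Regions are placed uniformly on a disk (or on a jittered grid), genotypes
are i.i.d. Bernoulli per locus and region, and the phenotype is

$$y_i = \mu_{base} + \sum_{causal}\big[a_d g_i + a_i \bar g_{N(i)} +
a_e\, g_i \bar g_{N(i)}\big] + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma^2),$$

with neighbour terms *averaged* over the adjacency neighbourhood so
effect sizes are comparable across node degrees, and noise resampled for
any region whose phenotype would be nonpositive (truncation would bias
ratio traits asymmetrically; with the defaults the resampling event is
negligible). Defaults emulate the motivating study design — 23 regions,
269 loci, mutant allele frequency 0.2 — with a baseline phenotype of 3
(an aneuploid ploidy level) and noise sd 0.5, both plausible for
region-level ploidy data. Genotypes carry no spatial autocorrelation by
default — the likelihood models genotype–phenotype association, not
clonal geometry — but a clustered-clone mode (mutant probability boosted
inside a random disk) is available to stress the permutation null.

What the generator does *not* emulate: copy-number structure, clonal
phylogenies, measurement error in the phenotype, and spatially varying
mutation rates. Passing tests therefore demonstrate the statistical
machinery under the stated model, not robustness to every feature of real
multi-region data.

## Problem sizes and experiment design

The shipped experiments use sizes chosen to make Monte-Carlo error small
relative to the quantity under test while staying desk-scale: the FWER
calibration runs 200 null tumors with 1,000 permutations each (the
binomial 95% band around 1% at 200 replicates is [0.1%, 3.6%]); recovery
runs 500 replicates of 100-region tumors at $\sigma = 0.5$ and mutant
frequency 0.35, where the OLS estimator's per-replicate spread leaves a
mean-bias Monte-Carlo error of about 0.01–0.025 trait units against the
0.05 acceptance band; power uses a planted direct effect of 2 at
$\sigma = 0.1$ on roughly 60 ordered pairs against the 99th percentile of
200 effect-specific permutations, 60 replicates. Grid-oracle,
decomposition and network checks are exact or near-exact and run in
seconds.

## Known limitations

* Both ordered copies of each edge enter the likelihood by default
  (`orderedPairs = "both"`); their non-independence is absorbed by the
  permutation null, never by analytic degrees of freedom, and a
  single-copy mode is provided.
* Effects are estimated and reported on the derivative-trait scale; no
  back-transformation to the original phenotypes of the two partners is
  attempted, since no such mapping is defined by the model.
* Coordinates are planar and distances Euclidean; no geodesic-through-
  tissue distances, no 3-D layouts.
* The strategy classification depends on one cohort-quantile parameter;
  it is a transparent operationalisation, not an estimate of payoffs.
* Whether published region-interaction figures thresholded network edges
  by score quantile, significance or curation is not stated in the
  source; the quantile rule is this package's documented choice, and the
  explicit edge-list input lets a user reproduce any fixed wiring.

## A small end-to-end run

```{r example, eval = FALSE}
sim <- simulateTumor(simulationConfig(
  nRegions = 23, nLoci = 60, mutantFreq = 0.3, sigma = 0.2,
  causal = data.frame(locus = 7, a_direct = 1.5, a_indirect = 0.5,
                      a_epistatic = 0.5),
  seed = 11))
tre <- experiment(sim)
res <- runGwas(tre, adjacency(sim), trait = "cooperation",
               nPerm = 1000, alpha = 0.01, seed = 11)
head(as.data.frame(res))

sig <- res$locus_id[res$significant]
decomposeLoci(suppressWarnings(filterSegregating(tre)), adjacency(sim),
              loci = sig, trait = "cooperation")

pairs <- deriveTrait(makeOrderedPairs(adjacency(sim), tre), "cooperation")
net <- buildNetwork(scoreEdges(pairs), edgeQuantile = 0.8,
                    nodes = regionIds(tre))
findHubs(annotateStrategies(net, phenotype(tre)), topK = 4)
```
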