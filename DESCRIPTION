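Package: tumorRewire
Title: Game-Theoretic Rewiring of Intratumoral Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models cell-cell interactions among spatially resolved tumor
    regions as an ecological game. Adjacent regions are paired on a spatial
    graph and their fitness phenotypes combined into derivative interaction
    traits (product = cooperation, ratio = altruism, inverse product =
    competition). A per-locus Gaussian likelihood over the four ordered
    genotype combinations of each pair drives a somatic-mutation association
    scan with genome-wide permutation thresholds, locus effects are
    decomposed into direct, indirect and across-cell epistatic components,
    and cooperative/competitive interaction networks with hub regions and
    ecological strategy labels are rewired from the pairwise scores. A
    synthetic-tumor generator with known genetic architecture supports
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
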