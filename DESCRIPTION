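Package: nicheassembly
Title: Niche Breadth, Assembly Processes, and Co-Occurrence Networks for
    Microbial Generalists and Specialists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify OTUs from a sample-by-OTU count table into
    habitat generalists, specialists, and neutral taxa with Levins niche
    breadth against quasiswap permutation nulls; to partition community
    assembly into deterministic and stochastic processes with beta-nearest
    taxon index (betaNTI) and abundance-based Raup-Crick (RC-Bray) null
    models; to fit the Sloan neutral community model; to compute
    checkerboard C-score standardized effect sizes; to build and summarise
    correlation co-occurrence networks (modularity, Zi-Pi node roles,
    keystone taxa); and to relate spatial (PCNM) and environmental blocks
    to richness with partial least squares path modelling. A synthetic
    community generator with known ground truth (planted generalists and
    specialists, Sloan-neutral tables, phylogenies with tunable
    phylogenetic signal, spatially autocorrelated covariates) makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    vegan,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
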