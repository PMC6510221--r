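Package: assemblyscope
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the balance of deterministic and stochastic processes
    structuring microbial communities from an OTU count table, a rooted
    phylogeny and sample metadata. Implements the beta-diversity null
    deviation, abundance-weighted beta-mean-nearest-taxon distance (betaMNTD)
    with its tip-shuffle null (betaNTI), the abundance-weighted Raup-Crick
    metric (RC_bray), threshold classification of sample pairs into assembly
    processes, permutation Mantel and pairwise-regression linkage to
    environmental gradients, and thresholded Spearman co-occurrence networks
    with modularity and Zi-Pi node roles. Ships a phylogenetically explicit
    community simulator so every inference stage is testable under known
    assembly regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    picante,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
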