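Package: ecoassembly
Title: Community Assembly Inference and Co-Occurrence Networks for
    Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from rarefied OTU tables. Fits the Sloan neutral community
    model to occupancy-abundance data, partitions pairwise community
    turnover into five assembly processes with the beta nearest taxon
    index (betaNTI) and Bray-Curtis based Raup-Crick null models, computes
    Levins' niche breadth, and builds Spearman/FDR co-occurrence networks
    with module detection, Zi-Pi keystone classification, Erdos-Renyi
    random baselines and natural-connectivity robustness curves. Includes
    a synthetic-community generator (neutral drift, Gaussian niche
    selection on a phylogenetically conserved trait, region-restricted
    source pools) that provides ground truth for every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
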