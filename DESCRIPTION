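Package: phylomint
Title: Phylogenetically Adjusted Metabolic Interaction Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reverse-ecology inference of microbial metabolic interactions
    from genome-scale metabolic models. Builds directed metabolite graphs
    from SBML models, identifies seed sets (exogenously acquired compounds)
    via source strongly connected components with per-compound confidence
    scores, computes asymmetric pairwise metabolic competition and
    complementarity indices, decouples the indices from phylogeny by binned
    Z-score normalization against patristic distances, flags Tukey outliers,
    and assembles a directed cooperation network exportable to Infomap for
    community detection. Includes a block-wise coding-sequence subsampler
    for assessing robustness of reconstructed networks to genome
    incompleteness, and synthetic fixture generators so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
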