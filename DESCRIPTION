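Package: mesoconn
Title: Construction and Network Analysis of Meso-Scale Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted directed connectomes from curated tract-tracing
    connection records organised under a hierarchical region ontology, and
    analyses them with the standard toolbox of meso-scale connectomics:
    network condensation, global small-world and scale-free diagnostics,
    per-region centrality tables including Shapley rates and cycle counts,
    directed 3- and 4-node motif censuses scored against degree-preserving
    rewiring nulls, pairwise distance/communicability/matching matrices,
    node and arc vulnerability via harmonic closeness, PCA of local
    connectivity features with Parzen-window densities, staged pathway
    searches, and a synthetic connectome generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
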