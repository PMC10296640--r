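Package: surfpatch
Title: Conserved Accessible Surface Patch Discovery on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies conserved accessible surface patches on protein
    structural models as proxies for functional interfaces. Autonomous
    structural modules are segmented from AlphaFold-style models by greedy
    modularity community detection on the inverse predicted-aligned-error
    graph; side-chain solvent accessibility and residue adjacency are derived
    from a 3-D Delaunay tessellation of heavy atoms; per-residue conservation
    is computed from orthologue alignments with guide-tree weighting; and
    connected high-centrality patches are extracted from a directed
    topology-accessibility-conservation graph via eigenvector centrality,
    minimum-variance score clustering, and one-sided Mann-Whitney scoring.
    Includes a deterministic synthetic-fixture generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
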