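Package: iinalign
Title: Greedy Alignment of Bipartite Interface-Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for aligning interface-interaction networks (IINs):
    bipartite graphs whose vertices are individual protein binding sites
    (peptide-recognition domains and their short ligand sites) and whose
    edges are physical interactions between sites. Implements the
    GreedyPlus aligner, which trades off vertex similarity against edge
    alignment through an additive Edge Alignment Weight, together with
    greedy and seed-and-extend baselines, a similarity-feature framework
    (topological centralities, graphlet degree signatures restricted to
    bipartite graphlets, Smith-Waterman peptide similarity, imported
    protein-level score tables), orthology-recovery evaluation metrics
    (represented protein orthologies, orthologous vertex pairs, edges
    aligned) with their data-dependent maxima, random-restart
    hill-climbing weight training, similarity-feature reduction, and a
    duplication-and-divergence simulator that generates paired networks
    with planted orthology for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
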