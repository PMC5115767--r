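Package: coevnet
Title: Coevolution- and Dynamics-Weighted Residue Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Integrated modelling of allosteric communication in protein
    kinases and other multi-domain proteins. Combines Gaussian network
    model (GNM) slow-mode analysis of a structure, mutual-information
    coevolution scores from a multiple sequence alignment
    (Kullback-Leibler conservation, cumulative MI, proximity MI), and
    generalized correlation coefficients from conformational ensembles
    into a weighted residue interaction network. Provides residue
    betweenness centrality, communication propensity from distance and
    proximity-MI fluctuations, network efficiency optimisation, and
    ensembles of Floyd-Warshall shortest communication paths with
    occupancies. Ships deterministic fixture generators (toy structures,
    planted-covariation alignments, GNM-sampled conformer ensembles) so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
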