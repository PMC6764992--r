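Package: netstates
Title: Network-Aware Wasserstein Metrics, Diffusion Maps and Mapper for
    Molecular Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised discovery of coherent transcriptomic states from
    gene expression matrices guided by a gene network. Samples are compared
    with an Earth Mover's (Wasserstein-1) distance whose ground metric is
    the shortest-path metric of the network, embedded with an
    anisotropically normalized diffusion map, summarized with the Mapper
    algorithm into a state graph, and decomposed into linear paths from
    which per-gene activation, inactivation and equivocal calls are made.
    Includes a seeded synthetic-data generator with planted states for
    end-to-end validation, and a file-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    clue,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
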