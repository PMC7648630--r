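Package: lamquant
Title: High-Throughput Lung Morphometry and Cluster Crosstalk Networks
Version: 0.1.0
Authors@R: person("lamquant", "maintainers", email = "maintainers@lamquant.org",
    role = c("aut", "cre"))
Description: Tools for quantitative lung histology and single-cell crosstalk
    analysis. Implements high-throughput mean linear intercept (MLI) and
    alveolar septal thickness (AST) morphometry of brightfield parenchyma
    images (Otsu binarization, morphological lumen filling, line-grid
    intercept counting, chord-length statistics), synthetic lung-parenchyma
    generators (square lattice and Voronoi tessellations) with known
    chord-length ground truth, ligand-receptor crosstalk graph inference
    between cell clusters from UMI count matrices (30 percent detection
    rule, directed weighted graph, hub scoring), and the accompanying
    group-comparison statistics (per-row Welch t tests with Holm-Sidak
    step-down correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    png,
    jpeg,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
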