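Package: marrowSOM
Title: Self-Organizing Map Reference Templates for Bone-Marrow Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Unsupervised immunophenotyping of bone-marrow flow cytometry data.
    Trains a batch self-organizing map (default 100 nodes) with a
    minimal-spanning-tree topology on merged normal bone-marrow samples
    (fluorescence channels plus side scatter), freezes the result as a
    per-panel reference template with node-level phenotype statistics and
    normal occupancy ranges, and maps patient samples onto the frozen
    reference to flag node-occupancy excess (blast populations, measurable
    residual disease) and deficit (lost maturation). Includes an FCS 3.0/3.1
    reader/writer, compensation and arcsinh transforms, rule-based node
    annotation, a synthetic bone-marrow simulator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotate.R'
    'cli.R'
    'compare.R'
    'fcs_io.R'
    'marrowSOM-package.R'
    'mst.R'
    'panels.R'
    'preprocess.R'
    'reference.R'
    'simulate.R'
    'som.R'
    'viz.R'
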