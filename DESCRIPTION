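Package: morphoscales
Title: Multi-Scale Neuron Morphometry from Whole-Brain Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale analysis of neuronal morphology: SWC
    reconstruction I/O and validation, L-Measure style morphometric features,
    dendritic microenvironment construction by proximity-weighted feature
    fusion, spatially tuned full-morphology clustering, axonal arbor
    decomposition by spectral clustering, primary axonal tract extraction and
    projection-motif classification, axonal varicosity detection from
    intensity and radius profiles, diversity-and-stereotypy (DS) matrices of
    cross-scale feature vectors, neurite co-occurrence density matrices with
    weighted rank correlation and regional module detection, and a
    segment-pruning filter suite for automated reconstructions. Seeded
    synthetic generators for every input class make all pipelines testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
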