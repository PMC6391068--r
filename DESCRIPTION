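Package: enscircuit
Title: Circuit Analysis of Myenteric Neuron Calcium Imaging and Gut Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for enteric nervous system circuit mapping by
    focal electrical stimulation and GCaMP calcium imaging. Extracts per-neuron
    dF/F0 transients from time-lapse movies, fingerprints responders across two
    consecutive stimulations into five signature classes (blocked, reduced,
    unchanged, increased, new), maps responder classes relative to the
    stimulation electrode, builds spatiotemporal diameter maps of colonic
    motility and detects migrating motor complexes, fits bimodal Gaussian
    mixtures to axonal projection lengths, quantifies voxel-level surface
    contact between soma and varicosity masks, and evaluates a monosynaptic
    two-neurons-per-fiber wiring model against regional neuron, fiber and
    responder counts. Includes synthetic-data generators with ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
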