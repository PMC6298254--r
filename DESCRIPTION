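Package: baitprey
Title: Spectral-Count Filtering and Network Construction for AP-MS Interactomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a stringent spectral-count filtering pipeline for
    bait-prey interactomics screens of the Virotrap/AP-MS kind: target-decoy
    false-discovery-rate estimation at the PSM level, assembly of a
    protein-by-experiment spectral-count matrix, control-based background
    removal, replicate summation with weak/strong interaction classes,
    one-hit-wonder removal, and construction of extensive and lean bait-prey
    interaction networks with TNF-dependent edge dynamics, reference-set
    (BioGRID-style) annotation and rescue.  Ships a synthetic-data generator
    emulating the experimental design (multiple baits, two conditions,
    replicates, shared contaminant background) so the whole pipeline is
    testable without downloads, and exporters for SIF, GraphML and PSI-MITAB
    2.5.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
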