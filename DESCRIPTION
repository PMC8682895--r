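Package: kinact
Title: Upstream Kinase Activity Analysis for Kinome Peptide Array Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of PamStation12/PamChip kinome peptide
    array experiments. Parses BioNavigator crosstab exports into a
    structured signal container, applies quality-control filters
    (baseline rescaling of negative values, saturation and low-signal
    filters, reference-peptide removal), models per-peptide phosphorylation
    kinetics as the linear slope of signal versus camera exposure time,
    computes chip-normalized log2 final signals and multi-cutoff
    differential phosphorylation, scores upstream kinase families with a
    random-sampling Z statistic against a peptide-permutation null, grows
    protein-protein-interaction networks around kinase hits, and provides
    a signal-to-noise robustness protocol. A synthetic-data generator
    emulates the full input format with a known-truth manifest so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    parallel
Config/testthat/edition: 3
RoxygenNote: 7.3.3
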