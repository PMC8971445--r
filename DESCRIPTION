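Package: mitorearr
Title: Gene-Order Rearrangement Analysis for Vertebrate Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of gene order in vertebrate
    mitochondrial genomes. Encodes annotated mitogenomes as signed circular
    gene orders over the canonical 37-gene vocabulary, detects and classifies
    rearrangements (duplications, deletions, inversions, translocations)
    against the ancestral vertebrate arrangement, screens apparent
    rearrangements for annotation errors using external sequence evidence,
    computes per-taxon and per-gene rearrangement proportions and hotspot
    regions, and identifies convergent gene arrangements across taxa via
    canonical architecture keys, rearrangement signatures, and
    breakpoint/inversion distances. Includes a synthetic mitogenome generator
    (stochastic transposition, reverse transposition, inversion,
    tandem-duplication-random-loss, duplication and deletion events, with
    injected annotation errors and ground-truth logs) and an end-to-end
    pipeline writing tabular reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'vocabulary.R'
    'architecture.R'
    'annotation-io.R'
    'detection.R'
    'statistics.R'
    'convergence.R'
    'simulate.R'
    'pipeline.R'
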