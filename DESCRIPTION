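Package: mapsweep
Title: Simulation-Based Testing of Read-Mapping Parameters for Degraded DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates sequencing reads with the hallmarks of degraded
    (ancient or archival) DNA -- short fragments with an exponential length
    tail, evolutionary divergence from the mapping reference, terminal
    cytosine deamination damage, and a user-defined mixture of endogenous
    and contaminant sources -- while recording the true origin of every
    read. Runs an arbitrary external read mapper over the Cartesian product
    of user-declared parameter values, then classifies each mapped read
    against its recorded origin to report per-run sensitivity, specificity
    and false-positive rate, before and after mapping-quality filtering.
    Includes a deterministic random-genome generator and an exhaustive
    gapless aligner so the full simulate-map-evaluate loop is testable
    without external references or mappers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rsamtools,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
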