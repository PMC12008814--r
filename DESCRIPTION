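Package: synlab
Title: Synthetic Regulatory Grammars and Interpretation of Base-Resolution TF Binding Models
Version: 0.1.0
Authors@R:
    person("Maintainer", "Synlab", email = "synlab@example.org", role = c("aut", "cre"))
Description: Simulates ChIP-nexus-like stranded, base-resolution transcription factor
    binding profiles from a configurable regulatory grammar (motif affinities, soft
    distance-dependent cooperativity, strictly spaced double motifs, indirect binding),
    trains and interrogates a small multi-task sequence-to-profile neural network,
    computes per-base contribution scores and contribution-weight-matrix (CWM) motifs,
    maps motif instances by CWM and PWM scanning, and runs in-silico syntax analyses:
    motif-injection enhancement statistics, distance sweeps, double-motif cooperativity,
    spacing perturbations, motif islands, IUPAC double-motif scans and minimal-mutation
    enhancer design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    optparse,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
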