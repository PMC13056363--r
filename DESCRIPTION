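Package: dasm
Title: Deep Amino-Acid Selection Models for Antibody Somatic Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Codon-level mutation-selection modelling of antibody affinity
    maturation. Factors somatic evolution on B-cell lineage trees into a
    fixed k-mer neutral somatic-hypermutation process (with multihit
    correction and light-chain rate scaling) and a learned selection
    process: a transformer encoder that maps an amino-acid sequence to
    per-site, per-amino-acid selection factors in a single forward pass.
    Provides parent-child pair (PCP) data structures and validators,
    per-PCP branch-length optimization, cyclic joint training, perplexity
    and variant-scoring statistics for deep mutational scans and
    multi-mutant libraries, and a generative simulator with planted
    parameters for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
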