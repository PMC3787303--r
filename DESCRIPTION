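Package: lowoxmeta
Title: Cross-Species Low-Oxygen Meta-Transcriptomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for meta-analysis of low-oxygen (hypoxia and
    anoxia) transcriptome experiments across species. Implements Bayesian
    regularized t-tests (Cyber-T style) with a beta-uniform mixture posterior
    probability of differential expression, MAS5-style detection-call
    filtering, PageMan-style over-representation analysis of hierarchical
    functional categories with signed z-scores, union-based ortholog mapping,
    cross-study consensus rules (conserved, condition-specific and
    species-specific categories), stress-overlap counting, and marker-gene
    identification. Ships a synthetic-data generator with planted ground
    truth so every stage is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
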