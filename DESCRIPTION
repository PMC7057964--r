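Package: antcoex
Title: Colony-Trait Coexpression Analysis of Single-Forager Brain Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking single-forager brain gene
    expression to colony-level behavioral and physiological traits in social
    insects. Provides TPM conversion and expression preprocessing (gene
    filtering, iterative outlier masking, quantile normalization,
    location-scale batch adjustment), per-gene expression-trait correlation
    with hierarchical colony sampling, sliding-threshold omnibus gene-set
    enrichment with Fisher's method, signed weighted coexpression networks
    with topological overlap, dynamic module detection with a
    pseudo-module permutation density filter, module eigengene and kME
    statistics, and integration of per-gene evolutionary constraint (dN/dS
    deciles) with network centrality. A synthetic-data generator with
    planted structure supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    limma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
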