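Package: stressomics
Title: Integrated Transcriptome and Proteome Analysis of Cnidarian Heat Stress
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of transcript (TPM) and iTRAQ proteome
    (spectral intensity) data from multi-strain heat-stress experiments on
    symbiotic cnidarians. Implements reference-standard-free two-step
    normalization of labelled proteomics runs (per-channel loading correction
    and per-gene median polish), detection filters, differential expression
    calling for transcripts and proteins (fold-change rule, Welch t-tests and
    a two-factor linear model), transcript-protein correlation and
    fold-change concordance analysis, GO term over-representation against an
    expressed-gene background, and normalization of reactive oxygen species
    assays. A synthetic-data module simulates coupled transcriptome/proteome
    studies with known ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'simulate.R'
    'proteome.R'
    'diffexpr.R'
    'integrate.R'
    'enrich.R'
    'phenotype.R'
    'io.R'
    'pipeline.R'
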