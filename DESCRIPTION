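Package: neurocycle
Title: Cell-Type-Resolved Circadian Transcriptome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for around-the-clock RNA-seq of sorted
    neuron populations: 3'-end window quantification of read positions,
    reads-per-million normalization, neuron-group enrichment
    classification (expression filter, fold-change rules, ANOVA with
    Tukey HSD and Benjamini-Hochberg correction), dual-method detection
    of cycling transcripts (Fourier F24 score with phase estimation and
    a nonparametric JTK-style rank test with an exact null), consensus
    high/low-confidence cycler calls, and phase-distribution summaries.
    Includes a synthetic time-course generator emulating a multi-group,
    two-replicate, six-timepoint circadian design with 3'-biased
    overdispersed count noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Transcriptomics, CircadianRhythms, GeneExpression, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'cycling.R'
    'enrichment.R'
    'io.R'
    'neurocycle-package.R'
    'phase.R'
    'pipeline.R'
    'quantify.R'
    'simulate.R'
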