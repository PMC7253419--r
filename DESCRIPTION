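Package: chromdyn
Title: Chromatin-State Dynamics, DNA Methylation and Regulatory-Element
    Analysis for Plant Epigenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative epigenome analysis on binned plant
    genomes: multivariate-Bernoulli hidden Markov chromatin-state
    segmentation with Poisson-test binarization and state annotation,
    binomial-test calling of 200-bp differentially methylated regions and
    their coupling to chromatin-state switches, tissue-pair state-switching
    and differential-signal statistics, classification of open-chromatin
    peaks into distal and proximal regulatory elements with loop-based gene
    categories, and multi-variety conservation and divergence statistics.
    Includes a hidden-state-driven synthetic epigenome generator with
    planted truth so that every analysis stage can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    MASS,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, HiddenMarkovModel, DNAMethylation, ChIPSeq,
    FunctionalGenomics, Sequencing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'chromdyn-package.R'
    'gene-features.R'
    'genome-io.R'
    'methylation.R'
    'pipeline.R'
    'regulatory-elements.R'
    'segmentation.R'
    'simulate.R'
    'state-dynamics.R'
    'utils.R'
    'variety-panel.R'
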