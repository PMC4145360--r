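Package: epiQMDR
Title: Two-Phase QMDR Screening and Entropy Networks for Epistasis in
    Quantitative Traits
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects gene-gene interactions affecting a quantitative
    endophenotype with a two-phase pipeline: within-gene exhaustive
    pairwise Quantitative Multifactor Dimensionality Reduction (QMDR)
    screening with permutation-based gene p-values, candidate reduction
    through a confidence-weighted functional gene network with
    hypergeometric gene-set enrichment, exhaustive two- to four-way QMDR
    over the surviving SNPs, and an entropy-based decomposition of the
    final model into independent, redundant and synergistic effects.
    Includes a fully seeded synthetic-data generator (Hardy-Weinberg
    genotypes, gene geometry, additive and purely epistatic phenotype
    architectures, functional-network and gene-set fixtures) so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, GeneSetEnrichment, NetworkInference,
    Epistasis
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'gwas-io.R'
    'qmdr.R'
    'permutation.R'
    'phase1.R'
    'functional-filter.R'
    'multiway.R'
    'entropy.R'
    'epiQMDR-package.R'
    'simulate.R'
    'pipeline.R'
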