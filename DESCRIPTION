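Package: primrose
Title: Population Genomics of Range Expansion and Mating-System Transitions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the population-genomic consequences of range
    expansion and the transition from heterostyly (outcrossing) to homostyly
    (selfing), built around the Primula vulgaris system. Provides VCF
    site/genotype filter cascades and 0-fold/4-fold degeneracy annotation, site
    frequency spectrum (SFS) construction with hypergeometric projection, a
    structured-coalescent simulator with split and size-change events,
    composite-likelihood demographic inference with AIC model selection and
    parametric-bootstrap confidence intervals, windowed diversity statistics
    (Watterson's theta, pi, Tajima's D) with accessibility correction, linkage
    disequilibrium decay and pruning, gamma distribution-of-fitness-effects
    estimation in Ne*s bins, a transposable-element sequencing-depth content
    statistic, and a synthetic-data generator emulating a serial-founder
    expansion with optional selfing demes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    pracma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
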