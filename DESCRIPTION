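Package: breedscan
Title: Windowed Selection Scans, LD Profiles and RAD Locus Selection for
    Breed-Origin Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline components for characterising the origin of a domestic
    breed from multi-population genotype panels: sliding-window heterozygosity
    with read-depth filtering, windowed Weir-Cockerham F_ST and the population
    branch statistic (PBS) with dual-scan candidate-region intersection,
    linkage-disequilibrium decay profiles summarised by an area-under-curve H
    statistic, in-silico restriction digest and neutral-locus selection for
    sequence-based demographic inference, conversion of mutation-scaled
    coalescent estimates (theta, tau, m) to effective sizes, calendar years
    and 2Nm, and a structured-coalescent simulator of a three-population
    wolf/indigenous-dog/breed demography used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
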