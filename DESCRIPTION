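Package: hymeth
Title: Cis/Trans Divergence and Inheritance of DNA Methylation in F1 Hybrids
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of DNA methylation differentiation between two hybridising
    species and their F1 hybrids from per-CpG bisulfite counts. Computes coverage
    filtered site and region methylation levels, metagene profiles and
    methylation-expression correlation profiles, calls differentially methylated
    regions (DMRs) and tissue-specific DMRs, performs Monte Carlo interval
    enrichment with empirical p-values and odds ratios, estimates allele-specific
    methylation at fixed-difference marker loci, classifies loci into seven
    cis/trans divergence categories with beta-regression tests, classifies
    promoter inheritance modes in hybrids on decorrelated axes, and provides
    genetic-epigenetic association statistics (Fst-Mdiff correlation profiles,
    between-groups PCA with permutation tests, preferential expression measures,
    paired DE-gene contrasts). A synthetic-data generator emulates the
    two-species plus F1-hybrid, five-tissue study design with beta-binomial
    count noise so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
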