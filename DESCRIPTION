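Package: methLandscape
Title: Whole-Genome Bisulfite Methylome Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for analysing the DNA methylation landscape of
    whole-genome bisulfite sequencing (WGBS) cohorts: global versus
    CpG-island methylation summaries, sliding-window hypomethylation
    profiling over partially methylated and highly methylated domains
    (PMDs/HMDs), DNA methylation valley (DMV) calling, enrichment of
    differentially methylated regions against a resampled random
    background, consensus clustering of variably methylated CpG islands
    with methylation-based sample grouping, read-level epiallele
    methylation entropy, and a promoter-methylation/expression screen
    for epigenetic regulators. A fully seeded synthetic-methylome
    generator with planted ground truth makes every stage testable
    without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
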