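Package: endoimprint
Title: Dormancy-Specific Genomic Imprinting Calls from Reciprocal-Cross
    Endosperm Allelic Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies maternally and paternally expressed imprinted genes
    (MEGs and PEGs) in the triploid Arabidopsis seed endosperm from
    reciprocal-cross RNA-seq allele-specific read counts. Aggregates per-SNP
    allelic counts to per-gene maternal and paternal totals, classifies genes
    with a three-criterion rule (maternal-fraction thresholds in both cross
    directions, a minimum read depth, and a two-tailed Fisher exact test
    against the 2:1 maternal:paternal dosage expected in triploid endosperm),
    partitions imprinted sets by seed-dormancy condition, and provides the
    downstream expression analyses: FPKM computation, relative-expression
    K-means clustering, dormancy-rank correlation classes, cold-response
    classes, a simplified exact-test differential call, and seed-coat (testa)
    contamination QC. A seeded synthetic-data generator emulates the
    reciprocal-cross allelic count structure for power and type-I-error
    analysis, and a configurable pipeline runs all stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Epigenetics, SNP, Sequencing
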