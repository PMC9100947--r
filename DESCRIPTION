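Package: ampliClone
Title: Clonal Architecture and Copy-Number Inference from Single-Cell
    DNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of targeted single-cell DNA amplicon
    sequencing (Tapestri-style) data: per-cell genotype calling with
    phred-scaled genotype quality from allele depths, zygosity-profile
    clone assignment with allele-dropout-aware clone-fraction
    estimation, longitudinal clonal-evolution (fish) tables, rare
    subclone detection, density-based clustering of allelic burden,
    and per-cell copy-number inference from amplicon read counts with
    low-efficiency artifact-amplicon filtering and multi-amplicon
    confirmation.  Includes a fully parameterised synthetic-data
    generator (clone trees, allele dropout, doublets, negative-binomial
    depth, subclonal copy losses) so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
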