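Package: mitotetrad
Title: Mitochondrial Inheritance, Heteroplasmy and Recombination in
    Fission-Yeast Tetrads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial genome inheritance in yeast tetrad
    dissection experiments genotyped by shotgun sequencing. Starting from a
    multi-sample VCF with per-sample reference/alternate observation counts
    (freebayes-style RO/AO fields) and a colony metadata table, the package
    filters variant sites, derives parental marker orientations per cross,
    computes per-colony heteroplasmy (minor observation fractions) and
    parent-of-origin fraction profiles along the mitochondrial genome, calls
    recombinant colonies and crossover breakpoint intervals, classifies
    tetrad segregation patterns against the expected 2:2 rule, and tests
    per-cross transmission bias with an exact binomial test. A ground-truthed
    simulator of tethered mitochondrial inheritance (with leakage, mixing,
    crossovers, spore inviability and self-mating) emits matching VCF and
    metadata files so the entire pipeline is verifiable without external
    data.
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
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
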