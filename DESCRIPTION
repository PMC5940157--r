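Package: gfblup
Title: Genomic Feature BLUP and Gene-Level Variance Partitioning for
    Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for panels of fully inbred lines with
    replicated phenotype records, in the style of studies on the Drosophila
    Genetic Reference Panel. Implements GBLUP and genomic-feature BLUP
    (GFBLUP) mixed models with average-information REML, genomic
    relationship matrices partitioned by gene-ontology feature sets,
    repeated 90/10 cross-validation of predictive ability with Welch tests
    and FDR control across GO terms, gene-level partitioning of genomic
    variance via the covariance association test (CVAT) with a
    circular-permutation empirical null, a marginal per-SNP regression
    scan, and a synthetic-data generator that emulates the inbred-panel
    study design for testing every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    lme4,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
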