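Package: thyroprofiler
Title: Expression-Based Profiling of Driver-Negative Thyroid Carcinomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterising thyroid carcinomas that lack
    mutations in the established driver genes. It filters annotated somatic
    variant calls (mapping quality, population allele frequency, normal-tissue
    subtraction, COSMIC cancer-gene rescue) and gene-fusion calls (FFPM and
    junction/spanning read support, normal-tissue blacklist), builds a
    normalised log2 fragments-per-million expression matrix, tests
    clusterability with a bootstrapped Hopkins statistic, chooses the number
    of expression clusters by bootstrapped multi-index consensus, clusters
    samples with WPGMA (McQuitty) linkage, assigns driver-negative samples to
    BRAF-like or RAS-like groups, and computes the BRAF-RAS score, thyroid
    differentiation score, ERK score and tumour mutation burden per sample.
    A synthetic-cohort generator with known ground truth makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    optparse
Config/testthat/edition: 3
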