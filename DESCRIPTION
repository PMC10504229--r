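Package: gwhap
Title: Genome-Wide Haplotype Association Analysis for Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A gene-based association toolkit for largely homozygous
    (inbred) genotype panels. Gene-body SNPs are collapsed into
    haplotype classes and each gene is tested against quantitative
    traits with an F-test of the haplotype-class factor in a linear
    model that includes principal components of genome-wide genotype
    dosages to correct for population stratification. Includes SNP
    quality-control filters (minor allele frequency, missingness),
    gene-interval SNP assignment, distance-based SNP thinning,
    centered-IBS kinship, a within-gene single-SNP scan that nominates
    the lowest-p SNP as the key natural variant, phenotype-table
    statistics for multi-trait panels, and a synthetic-data generator
    with planted haplotype effects so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
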