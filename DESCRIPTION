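Package: xciskew
Title: Detection of Skewed X-Chromosome Inactivation from Exome and
    Transcriptome Allelic Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls skewed X-chromosome inactivation (XCI) in females from
    paired exome and RNA-seq data without parental genotypes. Heterozygous
    X-linked sites from exome calls are intersected with RNA-seq pileups to
    obtain reference/alternate allele counts (CVAC); a three-tier
    beta-binomial reference model (position-specific, gene-specific, global)
    is fitted on a reference cohort with Laplace smoothing; patient sites are
    scored with a two-sided beta-binomial outlier p-value against the most
    specific available tier; and each sample is classified as skewed or
    random XCI from the percentage of significantly skewed sites, with a
    density-minimum rule for deriving the cohort threshold. Includes a
    synthetic-cohort simulator with known per-sample skew ratios so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
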