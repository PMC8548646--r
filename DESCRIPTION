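Package: JointScoreTest
Title: Joint Score Test for Paired Donor/Recipient Genetic Data in
    Transplantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-marker association testing for paired transplant
    donor/recipient genotype data. Implements the Joint Score Test (JST),
    which jointly tests recipient-genotype SNP effects and a gene-based
    donor/recipient matching-score effect on a binary or continuous
    transplant outcome, using eigen decomposition of the recipient-SNP
    score covariance as a dimension-reduction step. Provides the four
    per-SNP matching distance functions (identity-by-state,
    incompatibility, allogenomics mismatch, binary mismatch) and their
    gene-based aggregates with optional inverse-MAF weighting, comparator
    tests (joint GLM likelihood-ratio/score tests and SKAT-style
    quadratic-form tests with linear and IBS kernels), a
    latent-Gaussian-haplotype simulator with block linkage-disequilibrium
    structure for type-I error and power studies, and a gene-by-gene
    genome-scan pipeline with VCF/TSV input, BED region grouping, minor
    allele frequency filtering and Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
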