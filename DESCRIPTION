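Package: haploblup
Title: Genomic Prediction and Variance Component Estimation with SNP and
    Haplotype Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) and genomic
    restricted maximum likelihood (GREML) under a mixed model that can
    combine SNP additive effects, SNP dominance effects, and multi-allelic
    haplotype additive effects, where each haplotype block is treated as a
    locus and each distinct phased haplotype within the block as an allele.
    Includes utilities for haplotype blocking (by SNP count, by physical
    window, or from user intervals), haplotype genotype encoding,
    trace-normalized genomic relationship matrices with partitioned
    (multi-process) construction and a binary cache, a hybrid
    EM-REML/AI-REML estimator with dual tolerance stopping and heritability
    standard deviations, reliabilities and per-marker heritability
    partitioning, k-fold validation with observed and expected prediction
    accuracies, and a synthetic-data generator with known variance
    components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
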