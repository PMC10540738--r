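Package: metqtl
Title: Multi-Environment Trial Stability Genetics for Inbred Germplasm Panels
Version: 0.1.0
Authors@R:
    person("TCC", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of genotype-by-environment interaction in
    multi-environment trials (METs) of inbred germplasm collections: REML
    variance decomposition and broad-sense heritability with BLUPs for
    genotype and genotype-by-environment effects; WAASB and GGE
    average-environment-coordination stability indices; kinship-corrected
    single-marker mixed-model GWAS on trait means and stability plus two-stage
    genome-wide environment interaction scans; LD-based candidate regions,
    loci and QTL grouping; inheritance-mode (additive, dominant, recessive,
    overdominant) and QTL-by-environment interaction typing (magnitude change,
    conditional neutrality, antagonistic pleiotropy); D-prime solid-spine
    haplotype blocks with haplotype-trait association; diversity summaries and
    core-collection selection. Ships a synthetic-data generator emulating a
    GBS-genotyped tomato landrace panel so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
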