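Package: wishnet
Title: Epistatic SNP Interaction Networks for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide epistatic SNP-SNP interaction network analysis for
    quantitative traits such as feed efficiency. Reads PLINK-style text
    genotypes (PED/MAP, TPED/TFAM), applies standard genotype quality
    control (call rate, minor allele frequency, Hardy-Weinberg exact test),
    derives feed conversion ratio and residual feed intake phenotypes,
    performs single-SNP association with top-K selection and LD-block
    pruning, fits the pairwise interaction (heterogeneity) regression model
    to every SNP pair, builds a signed weighted interaction network with
    topological-overlap module detection, correlates module eigenSNPs with
    traits, extracts hub SNPs by soft connectivity, and maps them to genes
    from a local annotation. Includes a seeded genotype/phenotype simulator
    with LD blocks and planted epistatic effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
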