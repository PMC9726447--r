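Package: hybridpaint
Title: Ancestry Painting of Hybrid Subgenomes from Uniquely Shared Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns the subgenome of a hybrid strain to candidate source
    populations from a joint-genotyped multi-sample VCF. Implements a
    genotype-quality filter cascade (depth, genotype quality, SNP clusters,
    multiallelic sites, missingness, SNP-only selection), classification of
    each SNP site by uniquely shared alleles between the hybrid query and
    exactly one candidate population, block calling from runs of concordant
    sites with midpoint expansion to a full genome tiling, and per-population
    base-pair and percentage summaries. Also provides Random Repeated
    Haplotype Sampling (RRHS) pseudo-haplotype alignments for downstream tree
    inference, and a seeded synthetic-data generator (diverged source
    populations, mosaic hybrid, genotyping noise) with ground-truth tracts
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
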