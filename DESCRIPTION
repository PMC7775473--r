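Package: maluspop
Title: Population Genetics of Clonally Propagated Crop Germplasm Collections
Version: 0.1.0
Authors@R: person("Germplasm", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing SNP genotype panels from germplasm
    collections of clonally propagated crops such as apple (Malus).
    Provides a synthetic-data generator with ground truth (admixed
    populations, pedigrees, clones, triploids, selective sweeps, a binary
    trait), VCF/GFF ingestion and variant filtering, ploidy screening from
    per-individual heterozygosity, method-of-moments identity-by-descent
    estimation with clonal-group and first-degree relationship networks,
    projection principal component analysis with an f3 admixture test,
    Weir-Cockerham Fst and XP-EHH selection scans with candidate-gene
    windows and Fisher term enrichment, kinship-corrected mixed-model
    association with stepwise multi-locus refinement, a homozygosity
    resampling test, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
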