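Package: corepanel
Title: Core SNP Panel Selection and DNA Fingerprinting by Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a small panel of core SNPs able to uniquely distinguish
    every sample in a genotyped population using a genetic algorithm over
    candidate locus subsets, and emits per-sample DNA fingerprint codes.
    Includes VCF and genotype-matrix input/output, the three-stage candidate
    SNP filter (missingness, homozygote counts, adjacent-pair linkage
    disequilibrium), panel evaluation statistics (polymorphism information
    content, pairwise mismatch distances, panel-versus-full distance
    correlation), and a synthetic structured-population generator so the
    whole pipeline is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
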