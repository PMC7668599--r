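Package: snpsel
Title: Selection-Signature Scans from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for detecting signatures of selection
    in livestock SNP-array genotypes. Reads and writes PLINK text and binary
    genotype files, applies standard quality-control and LD-pruning filters,
    and computes within-population diversity statistics (observed and unbiased
    expected heterozygosity, bootstrap F_IS, rarefied allelic richness),
    consecutive-runs detection of runs of homozygosity (ROH) with
    genome-wide inbreeding (F_ROH) and population ROH islands, per-SNP
    Weir-Cockerham F_ST scans with top-fraction sweep calling, LD-based
    effective-population-size trajectories, Storey q-values for imported
    per-SNP scans, and multi-method consensus region calling with gene
    annotation. Includes seeded synthetic-data generators (Balding-Nichols
    population structure, planted autozygous and differentiated regions, and
    a forward Wright-Fisher simulator with recombination) so every stage is
    verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
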