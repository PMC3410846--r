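Package: cranioscan
Title: Landmark Morphometrics, Breed-Average GWAS, and Candidate-Variant
    Prioritization for Canine Skull Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for mapping quantitative trait loci
    underlying skull-shape variation in dog breeds. Implements generalized
    Procrustes superimposition and allometric correction of 3-D landmark data,
    shape principal components and breed-sex phenotype averages, single-marker
    and kinship-corrected mixed-model association on breed-average phenotypes,
    selective-sweep scans (observed heterozygosity ratios and Hudson F_ST in
    sliding windows), haplotype-sharing critical intervals with two-genome
    breakpoint refinement, and multi-criteria prioritization of candidate
    causal variants (genotype-quality masking, association percentile,
    conservation, and gene-context filters with codon-consequence annotation).
    Ships a seeded synthetic-data generator emulating the study design so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
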