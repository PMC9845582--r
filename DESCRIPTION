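Package: dippanel
Title: Forensic Evaluation of Biallelic Deletion/Insertion Polymorphism Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate forensic panels of biallelic deletion/insertion
    polymorphism (DIP) markers. Computes per-locus forensic parameters
    (polymorphism information content, matching probability, powers of
    discrimination and exclusion, typical paternity index, heterozygosities,
    Hardy-Weinberg exact tests, pairwise linkage-disequilibrium tests) and
    their across-panel combinations (CPM, TDP, CPE); simulates related
    genotype pairs under identity-by-descent models and runs likelihood-ratio
    kinship-discrimination studies; screens loci for ancestry informativeness;
    computes Weir-Cockerham F_ST and Nei's standard genetic distance with
    neighbor-joining, multidimensional-scaling and principal-component views;
    and evaluates biogeographic-ancestry assignment with a transparent
    allele-frequency likelihood classifier and exact binomial confidence
    intervals. Includes seeded synthetic-data generators for frequency
    spectra, Hardy-Weinberg genotypes, Balding-Nichols structured
    populations and related pairs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
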