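Package: markerdiv
Title: Genetic Diversity and Null-Allele Analysis for Co-Dominant Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing mixed SNP/SSR (microsatellite)
    marker panels in population genetic diversity studies. Implements the
    marker-QC filters used in reduced-representation marker discovery (read
    depth, minor allele frequency, call rate, flanking-sequence and primer
    constraints, perfect tandem-repeat scanning), per-locus and per-population
    diversity statistics (major allele frequency, allele and genotype counts,
    expected and observed heterozygosity, polymorphism information content,
    Wright's inbreeding coefficient), Hardy-Weinberg and linkage-disequilibrium
    screens, Brookfield-1 null-allele frequency estimation with allele-frequency
    correction and re-estimated inbreeding coefficients, Nei's standard genetic
    distance with UPGMA phenograms and allele-dosage PCA, and a Balding-Nichols
    multi-population genotype simulator for validating every stage without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
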