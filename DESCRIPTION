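Package: clinedom
Title: Hybrid Zone Cline Dynamics Under Partially Dominant Mating Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of a one-dimensional
    hybrid zone with assortative mating on a partially dominant mating trait,
    density-dependent reproduction and dispersal; smooth (penalized spline)
    cline fitting with center and width extraction and movement
    classification; an eight-scenario experiment grid testing displacement of
    mating-trait clines from the neutral genomic background; and a two-locus
    dominance/epistasis analysis of a continuous plumage-like phenotype from
    diagnostic-SNP genotype matrices (hybrid index, interclass
    heterozygosity, genotype-class phenotype lookup, inheritance-model
    comparison). Includes synthetic-data generators for cross pedigrees,
    phenotypes and transect samples so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
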