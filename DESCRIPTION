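Package: gblupgr
Title: Genomic Prediction from Group Records with Optimized Grouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and genetic evaluation of breeding
    programs that phenotype animals in groups rather than individually.
    Simulates a nested-mating population with linked biallelic loci,
    builds the VanRaden method-1 genomic relationship matrix, allocates
    full-sib offspring to equal-size phenotyping groups either at random
    (pedigree-based) or by supervised clustering that maximizes the mean
    genomic relationship within groups, estimates variance components by
    restricted maximum likelihood under GBLUP models for individual and
    for group-sum records, and evaluates accuracy, bias and coancestry of
    genomic breeding values. Includes scenario presets for sensitivity
    analyses on surplus offspring, group number, family size and genome
    size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
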